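site_fixture <- function() {
  cols <- c(paste0("A_b", rep(1:4, each = 2), "_t", 1:2),
            paste0("B_b", rep(1:4, each = 2), "_t", 1:2))
  design <- validate_design(tibble::tibble(
    run_id = cols, cell_line = rep(c("A", "B"), each = 8),
    bait = rep(c("A", "B"), each = 8), terminus = "N",
    bio_rep = rep(rep(1:4, each = 2), 2), tech_rep = rep(1:2, 8),
    is_control = FALSE
  ))
  v <- matrix(NA_real_, 3, 16, dimnames = list(NULL, cols))
  v[1, c("A_b1_t1", "A_b3_t2")] <- c(20, 21)   # 2 bio reps in line A
  v[2, c("A_b1_t1", "B_b2_t1")] <- c(20, 20)   # 1 bio rep per line
  v[3, ] <- rnorm(16, 20)                      # everywhere
  sites <- tibble::tibble(protein = c("NUP50", "NUP50", "NUP214"),
                          position = c(59L, 200L, 7L))
  sm <- intensity_matrix(v, tibble::tibble(
    group_id = paste0(sites$protein, "@", sites$position)),
    scale = "log2", sites = sites)
  list(sm = sm, design = design)
}

test_that("site filtering needs two biological replicates in some cell line", {
  fx <- site_fixture()
  kept <- filter_sites(fx$sm, fx$design, min_bio = 2)
  expect_setequal(kept$proteins$group_id, c("NUP50@59", "NUP214@7"))
  # idempotent
  again <- filter_sites(kept, fx$design, min_bio = 2)
  expect_equal(again$values, kept$values)
})

test_that("normalize-and-center zeroes site medians and ignores run-level shifts", {
  set.seed(2)
  v <- matrix(rnorm(60, 20), 6, 10,
              dimnames = list(NULL, paste0("r", 1:10)))
  v[sample(60, 8)] <- NA
  sites <- tibble::tibble(protein = paste0("P", 1:6), position = 1L)
  sm <- intensity_matrix(v, tibble::tibble(group_id = paste0("P", 1:6, "@1")),
                         scale = "log2", sites = sites)
  out <- normalize_center(sm)
  med <- apply(out$values, 1, median, na.rm = TRUE)
  expect_true(all(abs(med) < 1e-12))

  # constant input becomes all zeros
  cm <- sm; cm$values[] <- 7
  expect_true(all(normalize_center(cm)$values == 0))

  # per-run additive shifts do not change the output
  shifted <- sm
  shifted$values <- sweep(sm$values, 2, seq_len(10))
  expect_equal(normalize_center(shifted)$values, normalize_center(sm)$values)
})

test_that("domain mapping is inclusive, overlap-aware, and never drops a site", {
  sites <- tibble::tibble(protein = c("NUP50", "NUP50", "NUP50", "NUP214"),
                          position = c(59L, 50L, 300L, 10L))
  ann <- tibble::tibble(protein = c("NUP50", "NUP50", "NUP214"),
                        domain = c("BD2", "overlap", "beta-propeller"),
                        start = c(50L, 55L, 1L), end = c(70L, 60L, 400L))
  out <- map_sites_to_domains(sites, ann)
  lab59 <- out$domain[out$protein == "NUP50" & out$position == 59]
  expect_setequal(lab59, c("BD2", "overlap"))       # overlapping domains both report
  expect_equal(out$domain[out$protein == "NUP50" & out$position == 50], "BD2")  # inclusive start
  expect_equal(out$domain[out$protein == "NUP50" & out$position == 300],
               "linker/disordered")
  # label multiset at least as large as the site set; all sites present
  expect_gte(nrow(out), nrow(sites))
  expect_equal(nrow(dplyr::distinct(out[c("protein", "position")])), nrow(sites))

  expect_error(map_sites_to_domains(sites,
                                    tibble::tibble(protein = "NUP50", domain = "bad",
                                                   start = 10L, end = 5L)),
               "start <= end")
})

test_that("site counts track protein abundance for abundance-coupled simulations", {
  cfg <- sim_config(n_proteins = 400, n_ntrs = 6, n_controls = 2, n_bio = 4,
                    n_tech = 2, cargo_fraction = 0.5, delta = 3, n_complexes = 0,
                    mnar_mid = 25, mnar_steep = 1,
                    site_proteins = 50, sites_per_protein = 10,
                    site_on_cargo = TRUE)
  d <- simulate_design(cfg)
  tr <- simulate_truth(cfg, 3)
  m <- simulate_intensities(d, tr, cfg, 3)
  sm <- simulate_sites(d, tr, cfg, 3)
  ab <- dplyr::left_join(tidy(m), d[, c("run_id", "cell_line")], by = "run_id")
  ab <- dplyr::summarise(dplyr::group_by(ab, .data$group_id, .data$cell_line),
                         abundance = mean(.data$intensity, na.rm = TRUE),
                         .groups = "drop")
  ab <- dplyr::rename(ab, protein = "group_id")
  res <- site_count_vs_abundance(sm, d, ab, min_bio = 2)
  expect_gt(median(res$correlations$rho, na.rm = TRUE), 0.5)
  expect_gt(sum(!is.na(res$correlations$rho)), 20)
})

test_that("degenerate abundance input yields undefined correlations, not errors", {
  fx <- site_fixture()
  # single line -> fewer than 3 paired samples
  ab1 <- tibble::tibble(protein = c("NUP50", "NUP214"), cell_line = "A",
                        abundance = c(1, 2))
  res1 <- site_count_vs_abundance(fx$sm, fx$design, ab1)
  expect_true(all(is.na(res1$correlations$rho)))
  # constant abundance across lines
  ab2 <- tidyr::expand_grid(protein = c("NUP50", "NUP214"),
                            cell_line = c("A", "B"))
  ab2$abundance <- 5
  res2 <- site_count_vs_abundance(fx$sm, fx$design, ab2)
  expect_true(all(is.na(res2$correlations$rho)))
})
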