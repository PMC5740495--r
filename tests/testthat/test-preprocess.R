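test_that("identification filter applies peptide and replicate-coverage rules", {
  # 4 bio reps x 2 tech for one line, 4 x 2 for another
  cols <- c(paste0("A_b", rep(1:4, each = 2), "_t", 1:2),
            paste0("B_b", rep(1:4, each = 2), "_t", 1:2))
  design <- validate_design(tibble::tibble(
    run_id = cols,
    cell_line = rep(c("A", "B"), each = 8),
    bait = rep(c("A", "B"), each = 8),
    terminus = "N",
    bio_rep = rep(rep(1:4, each = 2), 2),
    tech_rep = rep(1:2, 8),
    is_control = FALSE
  ))
  v <- matrix(20, 3, 16, dimnames = list(c("seen3", "onepep", "seen2"), cols))
  # seen3: observed in bio reps 1-3 of line A only (one tech rep suffices)
  v["seen3", ] <- NA; v["seen3", c("A_b1_t1", "A_b2_t2", "A_b3_t1")] <- 20
  # seen2: observed in 2 bio reps of both lines
  v["seen2", ] <- NA
  v["seen2", c("A_b1_t1", "A_b2_t1", "B_b1_t1", "B_b2_t1")] <- 20
  m <- intensity_matrix(v, tibble::tibble(
    group_id = rownames(v), unique_peptides = c(5L, 1L, 5L)), scale = "log2")

  kept <- filter_identifications(m, design, min_unique = 2, min_bio = 3)
  expect_equal(kept$proteins$group_id, "seen3")
  expect_error(filter_identifications(m, design, min_bio = 5), "exceeds")
})

test_that("technical merging averages observed values and keeps NA only when all missing", {
  cols <- paste0("A_b", rep(1:2, each = 2), "_t", 1:2)
  design <- validate_design(tibble::tibble(
    run_id = cols, cell_line = "A", bait = "A", terminus = "N",
    bio_rep = rep(1:2, each = 2), tech_rep = rep(1:2, 2), is_control = FALSE
  ))
  v <- matrix(c(10, 12, 10, NA,
                NA, NA, 8, 8), 2, 4, byrow = TRUE,
              dimnames = list(c("x", "y"), cols))
  merged <- merge_technical(make_matrix(v), design)
  expect_equal(unname(merged$values["x", ]), c(11, 10))
  expect_true(is.na(merged$values["y", "A_b1"]))
  expect_equal(merged$values["y", "A_b2"], 8)
})

test_that("missing-value classification reproduces the 4-replicate rules", {
  cases <- tibble::tribble(
    ~obs_a, ~obs_b, ~class,
    4L, 4L, "COMPLETE",
    4L, 0L, "MNAR",
    3L, 1L, "MNAR",
    0L, 4L, "MNAR",
    3L, 3L, "MAR",
    4L, 3L, "MAR",
    2L, 2L, "EXCLUDED",
    4L, 2L, "EXCLUDED",
    1L, 2L, "EXCLUDED",
    0L, 0L, "EXCLUDED"
  )
  got <- classify_missing(cases$obs_a, cases$obs_b, n_a = 4, n_b = 4)
  expect_equal(as.character(got$class), cases$class)

  # symmetric up to swapping which side is depleted
  grid <- expand.grid(a = 0:4, b = 0:4)
  fwd <- classify_missing(grid$a, grid$b, 4, 4)$class
  rev <- classify_missing(grid$b, grid$a, 4, 4)$class
  expect_equal(as.character(fwd), as.character(rev))

  expect_error(classify_missing(5, 0, 4, 4), "observed counts")
})

test_that("MinDet imputation fills with the column minimum", {
  v <- matrix(c(18.1, 20.3, 25.0, NA,
                19.0, 21.0, 24.0, NA), 4, 2,
              dimnames = list(paste0("p", 1:4), c("c1", "c2")))
  target <- is.na(v)
  out <- impute_mnar_cells(v, target)
  expect_equal(out["p4", "c1"], 18.1)
  expect_equal(out["p4", "c2"], 19.0)
  # two MNAR cells in one column get identical values; imputed <= observed min
  v2 <- cbind(c1 = c(20, 22, NA, NA))
  rownames(v2) <- paste0("p", 1:4)
  out2 <- impute_mnar_cells(v2, is.na(v2))
  expect_equal(out2[3, 1], out2[4, 1])
  expect_true(all(out2[3:4, 1] <= min(v2[1:2, 1])))
  # a column with nothing observed cannot be imputed
  v3 <- cbind(c1 = c(NA_real_, NA_real_)); rownames(v3) <- c("a", "b")
  colnames(v3) <- "empty_run"
  expect_error(impute_mnar_cells(v3, is.na(v3)), "empty_run")
})

test_that("kNN imputation copies an identical neighbour and saturates at all eligibles", {
  v <- rbind(target = c(10, 11, 12, NA),
             twin   = c(10, 11, 12, 13),
             far    = c(30, 31, 32, 33))
  colnames(v) <- paste0("c", 1:4)
  tgt <- matrix(FALSE, 3, 4, dimnames = dimnames(v)); tgt["target", "c4"] <- TRUE
  out <- impute_mar_cells(v, tgt, k = 1)
  expect_equal(out["target", "c4"], 13)
  # k larger than the eligible pool averages all of them
  out2 <- impute_mar_cells(v, tgt, k = 10)
  expect_equal(out2["target", "c4"], mean(c(13, 33)))
})

test_that("kNN imputation recovers deleted values from a complete matrix", {
  set.seed(7)
  cfg <- sim_config(n_proteins = 500, n_ntrs = 3, n_controls = 1, n_bio = 4,
                    n_tech = 1, dropout = FALSE, n_complexes = 0)
  d <- simulate_design(cfg)
  m <- simulate_intensities(d, simulate_truth(cfg, 2), cfg, 2)
  v <- m$values
  del <- cbind(sample(nrow(v), 500, replace = TRUE),
               sample(ncol(v), 500, replace = TRUE))
  del <- del[!duplicated(del), ]
  truth_vals <- v[del]
  v[del] <- NA
  tgt <- matrix(FALSE, nrow(v), ncol(v)); tgt[del] <- TRUE
  imp <- impute_mar_cells(v, tgt, k = 10)
  err <- abs(imp[del] - truth_vals)
  sigma_b <- 0.5
  expect_gt(mean(err <= 2 * sigma_b), 0.85)
  expect_lt(median(err), 2 * sigma_b)
})

test_that("quantile normalization equalizes column distributions", {
  v <- cbind(c1 = c(1, 3), c2 = c(2, 4))
  rownames(v) <- c("a", "b")
  out <- quantile_normalize(v)
  expect_equal(unname(out), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  same <- cbind(c1 = c(5, 7, 9), c2 = c(5, 7, 9)); rownames(same) <- letters[1:3]
  expect_equal(quantile_normalize(same), same)

  set.seed(1)
  r <- matrix(rnorm(200), 50, 4,
              dimnames = list(paste0("p", 1:50), paste0("c", 1:4)))
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  r[1, 1] <- NA
  expect_error(quantile_normalize(r), "complete")
})

test_that("the per-comparison chain leaves no missing values among retained proteins", {
  cfg <- tiny_config(n_proteins = 500, mnar_mid = 23)
  d <- simulate_design(cfg)
  m <- simulate_intensities(d, simulate_truth(cfg, 4), cfg, 4)
  merged <- merge_technical(m, d)
  md <- attr(merged, "merged_design")
  lines <- unique(md$cell_line)[1:2]
  prep <- suppressWarnings(prepare_comparison(
    merged, md$column[md$cell_line == lines[1]],
    md$column[md$cell_line == lines[2]]))
  expect_false(anyNA(prep$values))
  expect_true(all(prep$classes$class[match(rownames(prep$values),
                                           prep$classes$group_id)] != "EXCLUDED"))
  # excluded proteins really are excluded
  excl <- prep$classes$group_id[prep$classes$class == "EXCLUDED"]
  expect_length(intersect(excl, rownames(prep$values)), 0)
})
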