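# Biotinylation-site-level analysis: replicate filtering, per-run
# normalization and per-site median centering, mapping of residue
# positions onto structural domain annotations, and the site-count versus
# protein-abundance comparison.

#' Filter sites by biological-replicate support
#'
#' A site is kept for a cell line when observed in at least `min_bio` of
#' its biological replicates (any technical replicate counts), and kept
#' globally when it passes in at least one cell line.
#'
#' @param sm a site-level `intensity_matrix` (runs unmerged).
#' @param design the study design.
#' @param min_bio minimum biological replicates (default 2).
#' @return The filtered site matrix.
#' @export
filter_sites <- function(sm, design, min_bio = 2) {
  design <- design[match(colnames(sm$values), design$run_id), ]
  obs <- !is.na(sm$values)
  key <- paste(design$cell_line, design$bio_rep, sep = "\r")
  bio_obs <- t(rowsum(t(obs) * 1L, key)) > 0
  line_of_key <- sub("\r.*$", "", colnames(bio_obs))
  bio_per_line <- t(rowsum(t(bio_obs) * 1L, line_of_key))
  keep <- apply(bio_per_line, 1, max) >= min_bio
  subset_matrix(sm, proteins = sm$proteins$group_id[keep])
}

#' Normalize and median-center site intensities
#'
#' Two location steps on the log2 scale: subtract each run's median over
#' its observed sites (run normalization), then subtract each site's
#' median over the runs where it is observed (centering). After centering
#' every site's median across observed runs is zero, and the output is
#' invariant to per-run additive shifts of the input.
#'
#' @param sm a log2 site-level `intensity_matrix`.
#' @return The normalized, centered site matrix (`scale = "normalized"`).
#' @export
normalize_center <- function(sm) {
  v <- sm$values
  run_med <- apply(v, 2, median, na.rm = TRUE)
  v <- sweep(v, 2, run_med)
  site_med <- apply(v, 1, median, na.rm = TRUE)
  v <- sweep(v, 1, site_med)
  sm$values <- v
  sm$scale <- "normalized"
  sm
}

#' Map biotinylation sites onto domain annotations
#'
#' A site at residue position p maps to every domain with
#' `start <= p <= end` (1-based, inclusive); overlapping domains all
#' report; positions outside every annotated domain are labelled
#' `"linker/disordered"`. No site is ever dropped.
#'
#' @param sites tibble with `protein` and `position` columns (e.g. the
#'   `sites` field of a site matrix).
#' @param annotation tibble with `protein`, `domain`, `start`, `end`.
#' @return Tibble (`protein`, `position`, `domain`), one row per matching
#'   label (possibly several per site).
#' @export
map_sites_to_domains <- function(sites, annotation) {
  if (any(annotation$start > annotation$end)) {
    stop_contract("domain annotations must satisfy start <= end")
  }
  hits <- inner_join(sites, annotation, by = "protein",
                     relationship = "many-to-many") |>
    filter(.data$position >= .data$start, .data$position <= .data$end) |>
    select("protein", "position", "domain")
  unhit <- dplyr::anti_join(sites, hits, by = c("protein", "position")) |>
    mutate(domain = "linker/disordered") |>
    select("protein", "position", "domain")
  arrange(dplyr::bind_rows(hits, unhit), .data$protein, .data$position)
}

#' Site counts versus protein abundance
#'
#' Per (protein, cell line): the number of sites passing the
#' replicate-support filter in that line, paired with the protein's
#' abundance (iBAQ-style) there; plus a per-protein Spearman correlation
#' of the two across lines. Proteins with fewer than 3 paired lines or
#' zero variance in either quantity report `NA`.
#'
#' @param sm a site-level `intensity_matrix`.
#' @param design the study design.
#' @param abundance tibble (`group_id`/`protein`, `cell_line`, `abundance`),
#'   e.g. per-line mean iBAQ.
#' @param min_bio replicate support needed to count a site (default 2).
#' @return List: `pairs` tibble (`protein`, `cell_line`, `n_sites`,
#'   `abundance`) and `correlations` tibble (`protein`, `rho`, `n_lines`).
#' @export
site_count_vs_abundance <- function(sm, design, abundance, min_bio = 2) {
  if ("group_id" %in% names(abundance) && !"protein" %in% names(abundance)) {
    abundance <- rename(abundance, protein = "group_id")
  }
  design <- design[match(colnames(sm$values), design$run_id), ]
  obs <- !is.na(sm$values)
  key <- paste(design$cell_line, design$bio_rep, sep = "\r")
  bio_obs <- t(rowsum(t(obs) * 1L, key)) > 0
  line_of_key <- sub("\r.*$", "", colnames(bio_obs))
  per_line <- t(rowsum(t(bio_obs) * 1L, line_of_key)) >= min_bio

  counts <- as_tibble(per_line * 1L)
  counts$protein <- sm$sites$protein
  counts <- counts |>
    tidyr::pivot_longer(-"protein", names_to = "cell_line",
                        values_to = "present") |>
    group_by(.data$protein, .data$cell_line) |>
    summarise(n_sites = sum(.data$present), .groups = "drop")

  pairs <- inner_join(counts, abundance, by = c("protein", "cell_line"))
  usable <- filter(pairs, is.finite(.data$abundance))
  correlations <- usable |>
    group_by(.data$protein) |>
    summarise(n_lines = dplyr::n(),
              rho = if (dplyr::n() < 3 ||
                        stats::sd(.data$n_sites) == 0 ||
                        stats::sd(.data$abundance) == 0) NA_real_ else
                suppressWarnings(cor(.data$n_sites, .data$abundance,
                                     method = "spearman")),
              .groups = "drop")
  list(pairs = pairs, correlations = correlations)
}
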