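# Identification filtering, technical-replicate merging, comparison-wise
# missing-value classification (MNAR / MAR), imputation and quantile
# normalization. Classification and imputation are per pairwise comparison:
# a protein may be excluded from one comparison and tested in another.

#' Filter protein identifications
#'
#' Retains protein groups identified by at least `min_unique` unique
#' peptides and observed in at least `min_bio` biological replicates of at
#' least one cell line. A biological replicate counts as observed if any of
#' its technical replicates has a value, so this runs before
#' [merge_technical()].
#'
#' @param m an `intensity_matrix` (technical replicates unmerged).
#' @param design the study design covering the matrix's runs.
#' @param min_unique minimum unique-peptide count (default 2).
#' @param min_bio minimum biological replicates with a value in one cell
#'   line (default 3).
#' @return The filtered `intensity_matrix`.
#' @export
filter_identifications <- function(m, design, min_unique = 2, min_bio = 3) {
  n_bio <- max(design$bio_rep)
  if (min_bio > n_bio) {
    stop_config("min_bio (%d) exceeds the design's biological replicates (%d)",
                min_bio, n_bio)
  }
  design <- design[match(colnames(m$values), design$run_id), ]
  if (anyNA(design$run_id)) stop_contract("matrix runs missing from design")

  obs <- !is.na(m$values)
  # per (cell line, bio rep): observed in any technical replicate
  key <- paste(design$cell_line, design$bio_rep, sep = "\r")
  bio_obs <- t(rowsum(t(obs) * 1L, key)) > 0
  line_of_key <- sub("\r.*$", "", colnames(bio_obs))
  bio_per_line <- t(rowsum(t(bio_obs) * 1L, line_of_key))
  coverage_ok <- apply(bio_per_line, 1, max) >= min_bio

  up <- m$proteins$unique_peptides
  peptide_ok <- !is.na(up) & up >= min_unique
  subset_matrix(m, proteins = m$proteins$group_id[coverage_ok & peptide_ok])
}

#' Merge technical replicates
#'
#' Collapses runs to one column per (cell line, biological replicate),
#' averaging the observed technical values on the log2 scale; a merged cell
#' is missing only when every technical replicate is missing. Merged
#' columns are named `<cell_line>_b<bio_rep>`.
#'
#' @param m a log2-scale `intensity_matrix`.
#' @param design the study design covering the matrix's runs.
#' @return An `intensity_matrix` with one column per biological replicate;
#'   attribute `merged_design` maps the new columns to their cell lines.
#' @export
merge_technical <- function(m, design) {
  if (m$scale == "raw") stop_contract("merge_technical expects log2-scale data")
  design <- design[match(colnames(m$values), design$run_id), ]
  if (anyNA(design$run_id)) {
    stop_contract("matrix contains runs absent from the design")
  }
  key <- sprintf("%s_b%d", design$cell_line, design$bio_rep)
  klev <- unique(key)
  vals <- vapply(klev, function(k) {
    rowMeans(m$values[, key == k, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m$values)))
  vals[is.nan(vals)] <- NA_real_
  colnames(vals) <- klev
  out <- intensity_matrix(vals, m$proteins, scale = m$scale, sites = m$sites)
  md <- dplyr::distinct(tibble(column = key, cell_line = design$cell_line,
                               bait = design$bait, terminus = design$terminus,
                               bio_rep = design$bio_rep,
                               is_control = design$is_control))
  attr(out, "merged_design") <- md
  out
}

#' Classify missing values for one pairwise comparison
#'
#' Given per-protein observed counts in the two sample groups, assigns one
#' of four classes. With the canonical 4-replicate groups: MNAR when one
#' group has at most one value and the other at least three (the missingness
#' tracks a real abundance difference); MAR when both groups are at most one
#' value short of complete and something is missing; COMPLETE when nothing
#' is missing; EXCLUDED otherwise (too little information to test). For
#' general group sizes the thresholds scale as `floor(n/4)` (mostly-missing)
#' and `ceiling(3 n/4)` (nearly-complete).
#'
#' @param obs_a,obs_b integer vectors of observed counts per protein.
#' @param n_a,n_b group sizes (defaults 4).
#' @return Tibble with `obs_a`, `obs_b` and `class` (factor MNAR / MAR /
#'   COMPLETE / EXCLUDED).
#' @export
classify_missing <- function(obs_a, obs_b, n_a = 4, n_b = n_a) {
  if (any(obs_a < 0 | obs_a > n_a) || any(obs_b < 0 | obs_b > n_b)) {
    stop_contract("observed counts must lie in [0, group size]")
  }
  lo_a <- max(1L, floor(n_a / 4)); hi_a <- ceiling(3 * n_a / 4)
  lo_b <- max(1L, floor(n_b / 4)); hi_b <- ceiling(3 * n_b / 4)

  complete <- obs_a == n_a & obs_b == n_b
  mnar <- (obs_a <= lo_a & obs_b >= hi_b) | (obs_b <= lo_b & obs_a >= hi_a)
  near <- obs_a >= n_a - max(1L, n_a - hi_a) & obs_b >= n_b - max(1L, n_b - hi_b)
  mar <- !complete & !mnar & near
  cls <- dplyr::case_when(complete ~ "COMPLETE",
                          mnar ~ "MNAR",
                          mar ~ "MAR",
                          .default = "EXCLUDED")
  tibble(obs_a = as.integer(obs_a), obs_b = as.integer(obs_b),
         class = factor(cls, levels = c("COMPLETE", "MNAR", "MAR", "EXCLUDED")))
}

# Observed counts per protein within a column set.
observed_counts <- function(values, cols) {
  rowSums(!is.na(values[, cols, drop = FALSE]))
}

#' Deterministic minimum imputation for MNAR cells
#'
#' Replaces each targeted missing cell by the minimum observed log2 value
#' of its run (column) - the "MinDet" rule: values missing because the
#' protein was below the detection limit are set to the lowest value the
#' run could quantify. Optionally a low quantile of the column instead of
#' the strict minimum.
#'
#' @param values numeric matrix (log2), `NA` missing.
#' @param target logical matrix of cells to impute (must be missing).
#' @param q quantile of the observed column values used as the imputed
#'   value (default 0 = minimum).
#' @return The matrix with targeted cells filled.
#' @export
impute_mnar_cells <- function(values, target, q = 0) {
  cols <- which(colSums(target) > 0)
  for (j in cols) {
    obs <- values[!is.na(values[, j]), j]
    if (!length(obs)) {
      stop_contract("run '%s' has no observed values to impute from",
                    colnames(values)[j])
    }
    values[target[, j], j] <- as.numeric(stats::quantile(obs, q))
  }
  values
}

#' k-nearest-neighbour imputation for MAR cells
#'
#' Each targeted missing cell is set to the mean of the same-column values
#' of the `k` nearest proteins. Nearness is root-mean-square Euclidean
#' distance over mutually observed columns (so rows sharing few columns are
#' not favoured); eligible neighbours must have an observed value in the
#' target column. With no eligible neighbour the row's own observed mean is
#' used and a warning logged.
#'
#' @param values numeric matrix (log2), `NA` missing.
#' @param target logical matrix of cells to impute.
#' @param k number of neighbours (default 10).
#' @return The matrix with targeted cells filled.
#' @export
impute_mar_cells <- function(values, target, k = 10) {
  rows <- which(rowSums(target) > 0)
  if (!length(rows)) return(values)
  observed <- !is.na(values)
  filled <- values

  # squared distances over mutually observed columns, by masked products:
  # sum_shared (x - y)^2 = x^2.m_y + y^2.m_x - 2 x.y  (masked terms)
  M <- observed * 1
  V <- values; V[!observed] <- 0
  V2 <- V^2

  fallback <- 0L
  for (chunk in split(rows, ceiling(seq_along(rows) / 1000))) {
    Tm <- M[chunk, , drop = FALSE]
    Tv <- V[chunk, , drop = FALSE]
    Tv2 <- V2[chunk, , drop = FALSE]
    d2 <- Tv2 %*% t(M) + Tm %*% t(V2) - 2 * (Tv %*% t(V))
    n_shared <- Tm %*% t(M)
    d <- sqrt(pmax(d2, 0) / pmax(n_shared, 1))
    d[n_shared == 0] <- Inf
    d[cbind(seq_along(chunk), chunk)] <- Inf

    for (ti in seq_along(chunk)) {
      i <- chunk[ti]
      ord <- order(d[ti, ])
      for (j in which(target[i, ])) {
        elig <- ord[observed[ord, j] & is.finite(d[ti, ord])]
        if (!length(elig)) {
          filled[i, j] <- mean(values[i, ], na.rm = TRUE)
          fallback <- fallback + 1L
          next
        }
        nn <- elig[seq_len(min(k, length(elig)))]
        filled[i, j] <- mean(values[nn, j])
      }
    }
  }
  if (fallback > 0) {
    rlang::warn(sprintf("kNN imputation fell back to the row mean for %d cell(s)",
                        fallback))
  }
  filled
}

#' Quantile-normalize a complete matrix
#'
#' Forces every column to share the same empirical distribution: the i-th
#' smallest value of each column becomes the mean of all columns' i-th
#' smallest values, with ties receiving the mean over their rank range.
#'
#' @param values complete numeric matrix (no missing values).
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(values) {
  if (anyNA(values)) {
    stop_contract("quantile normalization requires a complete matrix; impute first")
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Prepare one pairwise comparison
#'
#' Runs the per-comparison preprocessing chain on the two groups' merged
#' columns: classify missingness, drop EXCLUDED proteins, MinDet-impute the
#' depleted group of MNAR proteins, kNN-impute the remaining (at most one
#' per group) missing cells, then quantile-normalize the complete
#' submatrix.
#'
#' @param m merged `intensity_matrix` (one column per biological replicate).
#' @param cols_a,cols_b column names of the two groups.
#' @param k kNN neighbours for MAR imputation.
#' @param mindet_q quantile for MinDet (default 0, the column minimum).
#' @return List: `values` (complete normalized submatrix over retained
#'   proteins), `classes` (tibble `group_id`, `obs_a`, `obs_b`, `class` for
#'   all proteins), `cols_a`, `cols_b`.
#' @export
prepare_comparison <- function(m, cols_a, cols_b, k = 10, mindet_q = 0) {
  sub <- m$values[, c(cols_a, cols_b), drop = FALSE]
  obs_a <- observed_counts(sub, cols_a)
  obs_b <- observed_counts(sub, cols_b)
  cls <- classify_missing(obs_a, obs_b, n_a = length(cols_a), n_b = length(cols_b))
  cls <- dplyr::bind_cols(tibble(group_id = rownames(sub)), cls)

  keep <- cls$class != "EXCLUDED"
  vals <- sub[keep, , drop = FALSE]
  ka <- cls$class[keep]
  oa <- cls$obs_a[keep]; ob <- cls$obs_b[keep]

  observed <- !is.na(vals)
  # MNAR: fill the mostly-missing group's cells with the column minimum
  lo_a <- max(1L, floor(length(cols_a) / 4))
  lo_b <- max(1L, floor(length(cols_b) / 4))
  mnar_target <- matrix(FALSE, nrow(vals), ncol(vals),
                        dimnames = dimnames(vals))
  ia <- ka == "MNAR" & oa <= lo_a
  ib <- ka == "MNAR" & ob <= lo_b
  mnar_target[ia, cols_a] <- !observed[ia, cols_a, drop = FALSE]
  mnar_target[ib, cols_b] <- !observed[ib, cols_b, drop = FALSE]
  if (any(mnar_target)) vals <- impute_mnar_cells(vals, mnar_target, q = mindet_q)

  # remaining missing cells (MAR rows, and the nearly-complete side of MNAR)
  mar_target <- is.na(vals)
  if (any(mar_target)) vals <- impute_mar_cells(vals, mar_target, k = k)

  if (nrow(vals)) vals <- quantile_normalize(vals)
  list(values = vals, classes = cls, cols_a = cols_a, cols_b = cols_b)
}
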