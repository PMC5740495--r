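#' Proteins-by-runs quantification container
#'
#' An `intensity_matrix` holds a proteins x runs matrix of (usually log2)
#' MS intensities with `NA` marking missing values, alongside per-protein
#' metadata and a scale flag. It is the object passed between the reading,
#' preprocessing and testing stages; [tidy()] converts it to a long tibble
#' for plotting and joins.
#'
#' @param values numeric matrix, proteins x runs; `NA` encodes missing.
#' @param proteins tibble of per-protein metadata with at least `group_id`
#'   (unique), and optionally `gene_name`, `unique_peptides`, `is_reverse`,
#'   `is_contaminant`.
#' @param scale one of `"raw"`, `"log2"`, `"normalized"`.
#' @param sites optional tibble (`protein`, `position`) when rows are
#'   biotinylation sites rather than protein groups.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, proteins, scale = c("raw", "log2", "normalized"),
                             sites = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is_tibble(proteins)) proteins <- as_tibble(proteins)
  if (!"group_id" %in% names(proteins)) {
    stop_contract("protein metadata must contain a 'group_id' column")
  }
  if (nrow(proteins) != nrow(values)) {
    stop_contract("protein metadata rows (%d) do not match matrix rows (%d)",
                  nrow(proteins), nrow(values))
  }
  if (anyDuplicated(proteins$group_id)) {
    dup <- unique(proteins$group_id[duplicated(proteins$group_id)])
    stop_format("duplicate protein group ids: %s",
                paste(head(dup, 5), collapse = ", "))
  }
  rownames(values) <- proteins$group_id
  if (is.null(colnames(values))) {
    stop_contract("intensity matrix must have run ids as column names")
  }
  structure(
    list(values = values, proteins = proteins, scale = scale, sites = sites),
    class = "intensity_matrix"
  )
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d runs [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Run ids of an intensity matrix
#' @param x an `intensity_matrix`.
#' @return Character vector of run (column) identifiers.
#' @export
runs <- function(x) colnames(x$values)

#' Log2-transform a raw-scale intensity matrix
#'
#' @param m an `intensity_matrix` on the raw scale.
#' @return The matrix on the log2 scale; zeros must already be `NA`.
#' @export
log2_transform <- function(m) {
  if (m$scale != "raw") stop_contract("log2_transform expects a raw-scale matrix")
  if (any(m$values <= 0, na.rm = TRUE)) {
    stop_contract("non-positive intensities present; zeros must be encoded as missing")
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' @rdname tidy.intensity_matrix
#' @export
tidy.intensity_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "group_id")
  long <- tidyr::pivot_longer(long, -"group_id",
                              names_to = "run_id", values_to = "intensity")
  long$observed <- !is.na(long$intensity)
  long
}

#' Tidy an intensity matrix into a long tibble
#'
#' One row per (protein, run) with columns `group_id`, `run_id`,
#' `intensity` and `observed`.
#'
#' @param x an `intensity_matrix`.
#' @param ... unused.
#' @name tidy.intensity_matrix
NULL

#' Subset an intensity matrix by runs and/or proteins
#'
#' @param m an `intensity_matrix`.
#' @param proteins,runs character vectors of row / column ids to keep
#'   (default: keep all).
#' @return The subset `intensity_matrix`.
#' @export
subset_matrix <- function(m, proteins = NULL, runs = NULL) {
  keep_r <- if (is.null(proteins)) rownames(m$values) else proteins
  keep_c <- if (is.null(runs)) colnames(m$values) else runs
  missing_c <- setdiff(keep_c, colnames(m$values))
  if (length(missing_c)) {
    stop_contract("runs not present in matrix: %s", paste(missing_c, collapse = ", "))
  }
  idx <- match(keep_r, m$proteins$group_id)
  if (anyNA(idx)) {
    stop_contract("proteins not present in matrix: %s",
                  paste(head(keep_r[is.na(idx)], 5), collapse = ", "))
  }
  m$values <- m$values[idx, keep_c, drop = FALSE]
  m$proteins <- m$proteins[idx, ]
  if (!is.null(m$sites)) m$sites <- m$sites[idx, ]
  m
}
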