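# Calling the bait-interacting proteome (NIP) and the background proteome:
# each protein's one-sided p-values from the bait-vs-pooled-control
# comparisons are combined with the Simes method per direction, adjusted
# across proteins with Benjamini-Hochberg, and thresholded.

#' Simes combined p-value
#'
#' `min_i m p_(i) / i` over the ascending-sorted p-values, capped at 1.
#' Equals, by the closed-testing shortcut, the minimum Simes-adjusted
#' elementary p-value over all intersection hypotheses, and is small when
#' the protein is truly enriched in at least one comparison.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
simes_pvalue <- function(p) {
  if (!length(p)) stop_contract("Simes combination needs at least one p-value")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop_contract("p-values must lie in (0, 1]")
  }
  m <- length(p)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement, mapped back
#' to the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Call the bait-interacting and background proteomes
#'
#' Input is a long tibble of one-sided p-values from each bait-vs-control
#' comparison: `group_id`, `comparison`, `p_enriched` (small when the
#' protein is up in the bait sample) and `p_depleted` (small when up in the
#' controls); excluded (protein, comparison) pairs are simply absent. Per
#' protein and direction the available p-values are combined with Simes;
#' BH runs across proteins within each direction; a protein is labelled
#' `NIP` when its adjusted enriched-direction p is below `alpha`,
#' `BACKGROUND` for the depleted direction, `NEITHER` otherwise. Should
#' both directions pass, the smaller adjusted p wins and a conflict is
#' logged.
#'
#' @param pvals long tibble as described above.
#' @param alpha BH threshold (default 0.1).
#' @return A `nip_result` tibble: `group_id`, `m` (contributing
#'   comparisons), `p_nip`, `p_background`, `p_nip_adj`,
#'   `p_background_adj`, `label`.
#' @export
call_nip <- function(pvals, alpha = 0.1) {
  need <- c("group_id", "comparison", "p_enriched", "p_depleted")
  if (!all(need %in% names(pvals))) {
    stop_contract("call_nip needs columns: %s", paste(need, collapse = ", "))
  }
  if (!nrow(pvals)) stop_contract("no comparisons supplied")

  res <- pvals |>
    group_by(.data$group_id) |>
    summarise(m = dplyr::n(),
              p_nip = simes_pvalue(.data$p_enriched),
              p_background = simes_pvalue(.data$p_depleted),
              .groups = "drop")
  res$p_nip_adj <- bh_adjust(res$p_nip)
  res$p_background_adj <- bh_adjust(res$p_background)

  nip <- res$p_nip_adj < alpha
  bg <- res$p_background_adj < alpha
  both <- nip & bg
  if (any(both)) {
    rlang::warn(sprintf(
      "%d protein(s) significant in both directions; assigned by smaller adjusted p",
      sum(both)))
  }
  res$label <- dplyr::case_when(
    both & res$p_nip_adj <= res$p_background_adj ~ "NIP",
    both ~ "BACKGROUND",
    nip ~ "NIP",
    bg ~ "BACKGROUND",
    .default = "NEITHER"
  )
  structure(res, alpha = alpha, class = c("nip_result", class(res)))
}

#' Run all bait-vs-pooled-control comparisons
#'
#' Convenience driver: merges technical replicates, then compares every
#' fusion cell line against the pooled control columns and assembles the
#' long p-value table consumed by [call_nip()].
#'
#' @param m a log2 `intensity_matrix` (technical replicates unmerged).
#' @param design the study design.
#' @param k,mindet_q preprocessing parameters.
#' @return Long tibble (`group_id`, `comparison`, `p_enriched`,
#'   `p_depleted`, `fc`) plus the merged matrix in attribute `merged`.
#' @export
control_comparisons <- function(m, design, k = 10, mindet_q = 0) {
  merged <- merge_technical(m, design)
  md <- attr(merged, "merged_design")
  ctrl_cols <- md$column[md$is_control]
  if (length(ctrl_cols) < 2) stop_contract("need at least 2 pooled control columns")
  lines <- unique(md$cell_line[!md$is_control])
  out <- purrr::map(lines, function(ln) {
    cols_a <- md$column[md$cell_line == ln]
    cmp <- compare_groups(merged, cols_a, ctrl_cols, k = k, mindet_q = mindet_q)
    tibble(group_id = cmp$group_id,
           comparison = paste0(ln, "_vs_control"),
           p_enriched = cmp$p_a_greater,
           p_depleted = cmp$p_b_greater,
           fc = cmp$fc)
  }) |> dplyr::bind_rows()
  attr(out, "merged") <- merged
  out
}
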