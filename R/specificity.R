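# Interaction specificity: every fusion sample is compared against every
# other fusion sample; per (protein, sample) the significant one-sided
# p-values in the sample-enriched direction are multiplied into a score,
# combined with Fisher's method, and BH-adjusted globally. A protein
# enriched in many samples collects few significant pairwise p-values in
# any one of them and is thereby penalized relative to a single-sample
# interactor.

#' All-vs-all pairwise enrichment evidence
#'
#' Runs each unordered pair of fusion samples through the per-comparison
#' pipeline once and reads off both one-sided directions, keeping for
#' sample s and protein g the (p, fc) pairs from comparisons s-vs-s' with
#' one-sided p below `p_sig` in the s-enriched direction.
#'
#' @param m a log2 `intensity_matrix` (technical replicates unmerged).
#' @param design the study design.
#' @param p_sig significance cutoff for a pairwise p-value to enter the
#'   score (default 0.01).
#' @param adjust_within when `TRUE` (default) a pairwise p-value counts as
#'   significant when its BH-adjusted value within that directed comparison
#'   is below `p_sig`, and the adjusted value enters the score; `FALSE`
#'   selects on the raw one-sided p. Adjusted selection keeps chance
#'   replicate-level offsets, which recur across all of a sample's
#'   comparisons, from compounding in the Fisher combination.
#' @param k,mindet_q preprocessing parameters.
#' @return Long tibble (`sample`, `group_id`, `versus`, `p`, `fc`) of the
#'   significant enriched-direction evidence; attribute `n_samples`.
#' @export
pairwise_all <- function(m, design, p_sig = 0.01, adjust_within = TRUE,
                         k = 10, mindet_q = 0) {
  merged <- merge_technical(m, design)
  md <- attr(merged, "merged_design")
  lines <- unique(md$cell_line[!md$is_control])
  if (length(lines) < 2) stop_contract("pairwise specificity needs >= 2 fusion samples")

  pairs <- utils::combn(lines, 2)
  entries <- purrr::map(seq_len(ncol(pairs)), function(i) {
    s1 <- pairs[1, i]; s2 <- pairs[2, i]
    cmp <- compare_groups(merged,
                          md$column[md$cell_line == s1],
                          md$column[md$cell_line == s2],
                          k = k, mindet_q = mindet_q)
    p_up <- if (adjust_within) bh_adjust(cmp$p_a_greater) else cmp$p_a_greater
    p_dn <- if (adjust_within) bh_adjust(cmp$p_b_greater) else cmp$p_b_greater
    dplyr::bind_rows(
      tibble(sample = s1, group_id = cmp$group_id, versus = s2,
             p = clamp_p(p_up), fc = cmp$fc),
      tibble(sample = s2, group_id = cmp$group_id, versus = s1,
             p = clamp_p(p_dn), fc = -cmp$fc)
    )
  }) |> dplyr::bind_rows()
  out <- filter(entries, .data$p < p_sig)
  attr(out, "n_samples") <- length(lines)
  attr(out, "samples") <- lines
  out
}

#' Combine one sample's significant pairwise evidence
#'
#' For k significant p-values: `score = -log10(prod p)`, `avg_fc` the
#' arithmetic mean of the matching log2 fold changes, Fisher statistic
#' `X2 = -2 sum ln p` on 2k df and its upper-tail chi-square p-value.
#' An empty set gives score 0, `avg_fc` NA and Fisher p 1.
#'
#' @param p,fc vectors of significant p-values and their fold changes.
#' @return One-row tibble: `k`, `score`, `avg_fc`, `fisher_x2`, `fisher_p`.
#' @export
combine_specificity <- function(p, fc = rep(NA_real_, length(p))) {
  k <- length(p)
  if (k == 0) {
    return(tibble(k = 0L, score = 0, avg_fc = NA_real_,
                  fisher_x2 = 0, fisher_p = 1))
  }
  x2 <- -2 * sum(log(p))
  tibble(k = as.integer(k),
         score = -sum(log10(p)),
         avg_fc = mean(fc),
         fisher_x2 = x2,
         fisher_p = pchisq(x2, df = 2 * k, lower.tail = FALSE))
}

#' Global BH adjustment and significance flag
#'
#' BH across the full (protein x sample) table; pairs with adjusted Fisher
#' p below `alpha` are flagged significant.
#'
#' @param table specificity tibble with a `fisher_p` column.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return The table with `fisher_p_adj` and `significant` columns.
#' @export
adjust_and_flag <- function(table, alpha = 0.01) {
  table$fisher_p_adj <- bh_adjust(table$fisher_p)
  table$significant <- table$fisher_p_adj < alpha
  structure(table, alpha = alpha,
            class = unique(c("specificity_table", class(table))))
}

#' Specificity scores for every (protein, sample) pair
#'
#' Full driver: [pairwise_all()] evidence, [combine_specificity()] per
#' (protein, sample) - including pairs with no significant evidence, which
#' score 0 - then [adjust_and_flag()] globally.
#'
#' @inheritParams pairwise_all
#' @param alpha adjusted Fisher-p cutoff for the significance flag.
#' @return A `specificity_table` tibble: `sample`, `group_id`, `k`,
#'   `score`, `avg_fc`, `fisher_x2`, `fisher_p`, `fisher_p_adj`,
#'   `significant`.
#' @export
specificity_scores <- function(m, design, p_sig = 0.01, alpha = 0.01,
                               adjust_within = TRUE, k = 10, mindet_q = 0) {
  ev <- pairwise_all(m, design, p_sig = p_sig, adjust_within = adjust_within,
                     k = k, mindet_q = mindet_q)
  samples <- attr(ev, "samples")
  grid <- tidyr::expand_grid(sample = samples,
                             group_id = m$proteins$group_id)
  scored <- ev |>
    group_by(.data$sample, .data$group_id) |>
    summarise(combine_specificity(.data$p, .data$fc), .groups = "drop")
  out <- left_join(grid, scored, by = c("sample", "group_id")) |>
    mutate(k = dplyr::coalesce(.data$k, 0L),
           score = dplyr::coalesce(.data$score, 0),
           fisher_x2 = dplyr::coalesce(.data$fisher_x2, 0),
           fisher_p = dplyr::coalesce(.data$fisher_p, 1))
  adjust_and_flag(out, alpha = alpha)
}

#' @export
tidy.specificity_table <- function(x, ...) as_tibble(x)

#' @export
glance.specificity_table <- function(x, ...) {
  tibble(n_samples = dplyr::n_distinct(x$sample),
         n_proteins = dplyr::n_distinct(x$group_id),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha") %||% NA_real_)
}
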