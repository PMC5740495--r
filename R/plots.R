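# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_histogram geom_abline
#'   geom_hline labs facet_wrap scale_x_log10 theme_minimal
NULL

#' Plot missingness against intensity
#'
#' Histogram of observed log2 intensities with the per-bin fraction
#' missing, a quick check of the intensity-dependent (MNAR) dropout
#' pattern.
#'
#' @param m an `intensity_matrix`.
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_missingness <- function(m, bins = 40) {
  long <- tidy(m)
  ggplot(long[long$observed, ], aes(x = .data$intensity)) +
    geom_histogram(bins = bins, fill = "grey70") +
    labs(x = "log2 intensity (observed)", y = "cells",
         title = sprintf("%.1f%% of cells missing overall",
                         100 * mean(!long$observed))) +
    theme_minimal()
}

#' @export
autoplot.nip_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$p_nip, y = .data$p_background,
                 colour = .data$label)) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_x_log10() + ggplot2::scale_y_log10() +
    labs(x = "Simes p (bait-enriched direction)",
         y = "Simes p (control-enriched direction)",
         colour = NULL, title = "Interacting vs background proteome calls") +
    theme_minimal()
}

#' @export
autoplot.specificity_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df[df$k > 0, ], aes(x = .data$avg_fc, y = .data$score,
                             colour = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    facet_wrap(~sample) +
    labs(x = "average adjusted log2 FC", y = "specificity score",
         colour = "adj. Fisher p < cutoff") +
    theme_minimal()
}

#' @export
autoplot.propagation_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$f0, y = .data$f_corr)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "initial specificity score",
         y = "propagated, topology-corrected score") +
    theme_minimal()
}
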