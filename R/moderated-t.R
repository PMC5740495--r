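# Two-group one-sided moderated t-tests with empirical-Bayes variance
# shrinkage. Per-protein pooled variances are shrunk toward a prior
# (d0, s0^2) fitted by the method of moments on log variances; the
# moderated statistic is referred to a t distribution with d0 + d degrees
# of freedom.

#' Per-protein two-group summary statistics
#'
#' @param values complete numeric matrix (proteins x columns).
#' @param cols_a,cols_b column names of the two groups (each >= 2 columns).
#' @return Tibble: `group_id`, `fc` (mean A - mean B, log2), `s2` (pooled
#'   within-group variance), `df` (nA + nB - 2), `n_a`, `n_b`.
#' @export
fit_groups <- function(values, cols_a, cols_b) {
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop_contract("each group needs at least 2 columns")
  }
  if (anyNA(values[, c(cols_a, cols_b)])) {
    stop_contract("fit_groups requires complete data; run preprocessing first")
  }
  A <- values[, cols_a, drop = FALSE]
  B <- values[, cols_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2)
  ssb <- rowSums((B - mb)^2)
  tibble(group_id = rownames(values),
         fc = unname(ma - mb),
         s2 = unname(ssa + ssb) / (na + nb - 2),
         df = na + nb - 2,
         n_a = na, n_b = nb)
}

#' Fit the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse chi-square prior for the true
#' variances, from the observed pooled variances `s2` with common residual
#' df `d`. Writing `e_g = ln s2_g - digamma(d/2) + ln(d/2)`, the prior df
#' `d0` solves `trigamma(d0/2) = mean((e - mean(e))^2 * n/(n-1)) -
#' trigamma(d/2)` by bisection, and `s0^2 = exp(mean(e) + digamma(d0/2) -
#' ln(d0/2))`. When the left-hand target is at most `eps` the dispersion of
#' the variances is fully explained by chi-square sampling noise and the
#' prior is degenerate: `d0 = Inf`, `s0^2 = exp(mean(e))`.
#'
#' @param s2 vector of pooled variances (non-positive entries are dropped
#'   from the fit with a warning).
#' @param df common residual degrees of freedom.
#' @param eps guard for the trigamma inversion (default 1e-8).
#' @return List `d0`, `s02`, `n` (variances used).
#' @export
estimate_prior <- function(s2, df, eps = 1e-8) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop_contract("all variances are zero or non-finite; cannot fit prior")
  if (sum(ok) < length(s2)) {
    rlang::warn(sprintf("%d non-positive variance(s) dropped from the prior fit",
                        length(s2) - sum(ok)))
  }
  if (sum(ok) < 50) {
    rlang::warn("fewer than 50 variances; the prior fit may be unstable")
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  target <- mean((e - ebar)^2 * n / (n - 1)) - trigamma(df / 2)
  if (target <= eps) {
    return(list(d0 = Inf, s02 = exp(ebar), n = n))
  }
  # trigamma is strictly decreasing: bisection on half-df in (1e-3, 1e3)
  f <- function(h) trigamma(h) - target
  lo <- 1e-3; hi <- 1e3
  if (f(lo) < 0) return(list(d0 = 2 * lo, s02 = exp(ebar + digamma(lo) - log(lo)), n = n))
  if (f(hi) > 0) return(list(d0 = Inf, s02 = exp(ebar), n = n))
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  h <- (lo + hi) / 2
  list(d0 = 2 * h, s02 = exp(ebar + digamma(h) - log(h)), n = n)
}

#' One-sided moderated t-test
#'
#' Shrinks each protein's variance toward the prior,
#' `s2_tilde = (d0 s0^2 + d s2) / (d0 + d)`, forms
#' `t = fc / (s_tilde * sqrt(1/nA + 1/nB))` and takes the upper tail of the
#' t distribution with `d0 + d` df in the requested direction (normal tail
#' when `d0` is infinite). `d0 = 0` reproduces the ordinary pooled t-test.
#'
#' @param fit tibble from [fit_groups()].
#' @param prior list from [estimate_prior()] (or any `d0`/`s02` pair).
#' @param direction `"A_greater"` (p small when A is enriched) or
#'   `"B_greater"`.
#' @return `fit` with columns `s2_post`, `t_mod`, `p` added; attributes
#'   `d0`, `s02`, `direction`. Class `moderated_fit`.
#' @export
moderated_test <- function(fit, prior, direction = c("A_greater", "B_greater")) {
  direction <- match.arg(direction)
  d0 <- prior$d0; s02 <- prior$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(fit))
    df_tot <- Inf
  } else {
    s2_post <- (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
    df_tot <- d0 + fit$df
  }
  se <- sqrt(s2_post * (1 / fit$n_a + 1 / fit$n_b))
  t_mod <- fit$fc / se
  t_mod[se == 0] <- sign(fit$fc[se == 0]) * Inf
  t_mod[se == 0 & fit$fc == 0] <- 0
  stat <- if (direction == "A_greater") t_mod else -t_mod
  p <- if (is.infinite(d0)) pnorm(stat, lower.tail = FALSE)
       else pt(stat, df = df_tot, lower.tail = FALSE)
  out <- fit
  out$s2_post <- s2_post
  out$t_mod <- t_mod
  out$p <- clamp_p(p)
  structure(out, d0 = d0, s02 = s02, direction = direction,
            class = c("moderated_fit", class(fit)))
}

#' Full two-group comparison on a merged matrix
#'
#' Chains [prepare_comparison()], [fit_groups()], [estimate_prior()] and
#' [moderated_test()] in both directions for one pair of sample groups.
#'
#' @param m merged `intensity_matrix`.
#' @param cols_a,cols_b merged column names of the two groups.
#' @param k,mindet_q preprocessing parameters (see [prepare_comparison()]).
#' @return A `comparison_result` tibble: `group_id`, `class`, `fc`, `s2`,
#'   `df`, `s2_post`, `t_mod`, `p_a_greater`, `p_b_greater`; attributes
#'   `d0`, `s02`, `n_a`, `n_b`.
#' @export
compare_groups <- function(m, cols_a, cols_b, k = 10, mindet_q = 0) {
  prep <- prepare_comparison(m, cols_a, cols_b, k = k, mindet_q = mindet_q)
  if (!nrow(prep$values)) {
    stop_contract("no proteins retained for this comparison")
  }
  fit <- fit_groups(prep$values, prep$cols_a, prep$cols_b)
  prior <- estimate_prior(fit$s2, df = fit$df[1])
  up <- moderated_test(fit, prior, "A_greater")
  down <- moderated_test(fit, prior, "B_greater")
  out <- tibble(group_id = fit$group_id,
                fc = fit$fc, s2 = fit$s2, df = fit$df,
                s2_post = up$s2_post, t_mod = up$t_mod,
                p_a_greater = up$p, p_b_greater = down$p)
  out <- left_join(out, select(prep$classes, "group_id", "class"), by = "group_id")
  structure(out, d0 = prior$d0, s02 = prior$s02,
            n_a = length(cols_a), n_b = length(cols_b),
            class = c("comparison_result", class(out)))
}

#' @export
tidy.moderated_fit <- function(x, ...) as_tibble(x)

#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = attr(x, "d0"), s02 = attr(x, "s02"),
         direction = attr(x, "direction"), n_proteins = nrow(x))
}

#' @export
tidy.comparison_result <- function(x, ...) as_tibble(x)

#' @export
glance.comparison_result <- function(x, ...) {
  tibble(d0 = attr(x, "d0"), s02 = attr(x, "s02"),
         n_a = attr(x, "n_a"), n_b = attr(x, "n_b"), n_proteins = nrow(x))
}
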