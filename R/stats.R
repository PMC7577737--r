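#' One-sample t-test
#'
#' Classical two-sided one-sample t-test of the mean against `mu0`, fronting
#' `stats::t.test` with the package's result container.
#'
#' @param values numeric vector, n >= 2, nonzero variance.
#' @param mu0 null mean (default 0).
#' @return list of class `wave_test` with `statistic`, `df`, `p_value`,
#'   `estimate`, `conf_low`, `conf_high`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values")
  if (stats::sd(values) == 0) stop("zero variance: t-test undefined")
  tt <- stats::t.test(values, mu = mu0)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, estimate = unname(tt$estimate),
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2]),
            class = "wave_test")
}

#' @export
print.wave_test <- function(x, ...) {
  cat(sprintf("t(%g) = %.4f, p = %.4g, mean = %.4f [%.4f, %.4f]",
              x$df, x$statistic, x$p_value, x$estimate, x$conf_low,
              x$conf_high))
  if (!is.null(x$bf10)) cat(sprintf(", BF10 = %.3g", x$bf10))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control: with `m` p-values sorted ascending, all hypotheses up
#' to the largest `k` with `p(k) <= k * q / m` are rejected. Adjusted
#' p-values come from `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list of class `fdr_result` with `p`, `p_adjusted`, `rejected`
#'   (logical), `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  adj <- stats::p.adjust(pvalues, method = "BH")
  structure(list(p = pvalues, p_adjusted = adj, rejected = adj <= q, q = q),
            class = "fdr_result")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation with the classical t-based two-sided p-value,
#' fronting `stats::cor.test`.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Moment-by-moment forward-backward coupling
#'
#' Pearson correlation between the forward and backward net wave amounts
#' across the windows whose start time falls in the given post-injection
#' minute range, the moment-by-moment measure of how the two directions
#' trade off.
#'
#' @param estimates a `wave_estimates` data frame.
#' @param minutes `c(from, to)` in post-injection minutes; windows with
#'   `t_start` in `[60*from, 60*to)` seconds enter (default minutes 2-5).
#' @return list with `r`, `p_value`, `n` (windows used).
#' @export
fw_bw_coupling <- function(estimates, minutes = c(2, 5)) {
  sel <- estimates$t_start >= 60 * minutes[1] &
    estimates$t_start < 60 * minutes[2]
  if (sum(sel) < 3L) stop("fewer than 3 windows in the requested range")
  pearson_r(estimates$fw_db[sel], estimates$bw_db[sel])
}

#' Default-prior (JZS) one-sample Bayes factor
#'
#' Bayes factor BF10 for a nonzero mean against a point null, with a Cauchy
#' prior (scale `cauchy_scale`) on the standardized effect size. The marginal
#' likelihood under H1 is computed by numerical integration of the
#' noncentral-t likelihood over the Cauchy prior; BF10 > 1 favours a nonzero
#' mean. Depends on the data only through the t statistic and n, so it is
#' invariant to rescaling the values.
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @param mu0 null mean (default 0).
#' @param cauchy_scale prior scale on the standardized effect (default 0.707).
#' @return BF10 (positive scalar).
#' @export
jzs_bf10 <- function(values, mu0 = 0, cauchy_scale = 0.707) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance")
  t <- (mean(values) - mu0) / (stats::sd(values) / sqrt(n))
  jzs_bf10_t(t, n, cauchy_scale)
}

# BF10 from the t statistic: integrand over the Cauchy prior on delta.
# The noncentral density emits routine precision warnings at large
# noncentrality; its accuracy is ample for the ~1e-8 integration tolerance.
jzs_bf10_t <- function(t, n, cauchy_scale = 0.707) {
  df <- n - 1
  lik <- function(delta)
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n)))
  prior <- function(delta) stats::dcauchy(delta, scale = cauchy_scale)
  m1 <- stats::integrate(function(d) lik(d) * prior(d), -Inf, Inf,
                         rel.tol = 1e-8, stop.on.error = FALSE)
  if (m1$message != "OK" && m1$value <= 0)
    stop("numeric error integrating the marginal likelihood")
  m1$value / stats::dt(t, df)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power under the noncentral t distribution: with noncentrality
#' `ncp = (mu1 - mu2) / (sd * sqrt(2 / n))` and `df = 2n - 2` degrees of
#' freedom, the probability that `|T|` exceeds the two-sided critical value.
#' Both rejection tails are included, so the power equals `alpha` exactly
#' when the means coincide.
#'
#' @param mu1,mu2 group means.
#' @param sd common standard deviation (> 0).
#' @param n_per_group subjects per group (>= 2).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @return power in `[0, 1]`.
#' @export
two_sample_power <- function(mu1, mu2, sd, n_per_group, alpha = 0.05) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  if (n_per_group < 2) stop("need n >= 2 per group")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- n_per_group
  ncp <- (mu1 - mu2) / sd * sqrt(n^2 / (2 * n))
  df <- 2 * n - 2
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}
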