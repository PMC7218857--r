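#' Normalized root-mean-square error
#'
#' RMSE between a test and a reference series, divided by the reference
#' range `max(ref) - min(ref)`. Range normalization keeps the value
#' dimensionless and comparable across joints with different ranges of
#' motion, and it is invariant under a common shift of both series.
#'
#' @param test,ref equal-length numeric series.
#' @return non-negative scalar.
#' @export
nrmse <- function(test, ref) {
  check_pair(test, ref)
  rng <- max(ref) - min(ref)
  if (rng <= 0) stop("constant reference: zero range", call. = FALSE)
  sqrt(mean((test - ref)^2)) / rng
}

#' Pearson correlation between a test and a reference series
#'
#' @param test,ref equal-length numeric series, each non-constant, n >= 2.
#' @return correlation in [-1, 1].
#' @export
pearson_rho <- function(test, ref) {
  check_pair(test, ref, min_n = 2L)
  if (stats::sd(test) == 0 || stats::sd(ref) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stats::cor(test, ref)
}

#' Cross-approximate entropy (XApEn)
#'
#' Template-matching asynchrony statistic between two series. Both series
#' are standardized (centered, unit variance; a zero-variance series is
#' centered only), then for embedding dimension `m` each length-`m`
#' template of `test` is matched against every length-`m` template of
#' `ref` under the Chebyshev (maximum-coordinate) distance with tolerance
#' `r`:
#' \deqn{\Phi^m(r) = \mathrm{mean}_i \log C_i^m(r), \quad
#'       C_i^m(r) = \#\{j : d(x_i, y_j) \le r\} / (N - m + 1)}
#' and \eqn{XApEn(m, r) = \Phi^m(r) - \Phi^{m+1}(r)}. Templates with no
#' match (possible in cross-comparison) are excluded from the average at
#' their level. Lower values mean more synchronous pattern structure;
#' identical series with `r > 0` score near 0. XApEn is non-increasing in
#' `r`.
#'
#' @param test,ref equal-length numeric series, length >= m + 2.
#' @param m embedding dimension (default 2).
#' @param r tolerance on the standardized scale (default 0.2, i.e. 0.2
#'   standard deviations of the standardized reference).
#' @param standardize standardize both series first (default TRUE).
#' @return non-negative scalar (up to floating point).
#' @export
xapen <- function(test, ref, m = 2L, r = 0.2, standardize = TRUE) {
  check_pair(test, ref, min_n = m + 2L)
  if (r <= 0) stop("tolerance r must be positive", call. = FALSE)
  if (standardize) {
    test <- standardize_series(test)
    ref <- standardize_series(ref)
  }
  phi_m(test, ref, m, r) - phi_m(test, ref, m + 1L, r)
}

standardize_series <- function(x) {
  s <- stats::sd(x)
  if (s > 0) (x - mean(x)) / s else x - mean(x)
}

# average log conditional regularity of m-templates of x matched in y
phi_m <- function(x, y, m, r) {
  n_t <- length(x) - m + 1L
  # Chebyshev distances between all template pairs, built coordinate-wise
  D <- abs(outer(x[seq_len(n_t)], y[seq_len(n_t)], "-"))
  if (m > 1L) {
    for (k in 2:m) {
      idx <- (k - 1L) + seq_len(n_t)
      D <- pmax(D, abs(outer(x[idx], y[idx], "-")))
    }
  }
  counts <- rowSums(D <= r)
  matched <- counts > 0
  if (!any(matched)) {
    stop("no template matches at tolerance r; increase r", call. = FALSE)
  }
  mean(log(counts[matched] / n_t))
}

#' Drift slope of an angle series
#'
#' Ordinary least-squares slope of the series against time: the linear
#' trend of the signal, read as the orientation drift rate (deg/s) under
#' the assumption that integration drift accumulates linearly over a
#' trial.
#'
#' @param series angle series, deg.
#' @param t time vector, s (default uniform unit-rate index; pass real
#'   times for a physical slope).
#' @param trim_s seconds to drop from each end before fitting, excluding
#'   gait acceleration/deceleration transients (0 disables).
#' @return slope, deg/s.
#' @export
drift_slope <- function(series, t = seq_along(series) - 1, trim_s = 0) {
  if (length(series) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(t) != length(series)) stop("time vector length mismatch", call. = FALSE)
  if (trim_s > 0) {
    keep <- t >= (min(t) + trim_s) & t <= (max(t) - trim_s)
    if (sum(keep) < 2L) stop("trim leaves fewer than 2 samples", call. = FALSE)
    series <- series[keep]; t <- t[keep]
  }
  ols_slope(series, t)
}

#' Ratio of test to reference drift error
#'
#' `|slope(test)| / |slope(ref)|` on a shared time base: how many times
#' faster the test system drifts than the reference system.
#'
#' @param test_series,ref_series equal-length angle series, deg.
#' @param t shared time vector, s.
#' @return non-negative ratio.
#' @export
drift_ratio <- function(test_series, ref_series, t = seq_along(test_series) - 1) {
  s_ref <- drift_slope(ref_series, t)
  if (s_ref == 0) stop("zero reference drift slope", call. = FALSE)
  abs(drift_slope(test_series, t)) / abs(s_ref)
}

#' Drift increment across a 180-degree turn
#'
#' Compares the absolute drift slope after the turn with the slope before
#' it: `100 * (|slope_after| - |slope_before|) / |slope_before|`, in
#' percent. A value of 100 means the drift rate doubled with the turn.
#'
#' @param series angle series, deg.
#' @param t time vector, s.
#' @param turn_index 1-based index of the first post-turn sample; must be
#'   strictly inside the series with at least 2 samples on each side.
#' @return increment in percent.
#' @export
turn_drift_increment <- function(series, t, turn_index) {
  n <- length(series)
  if (turn_index <= 2L || turn_index > n - 1L) {
    stop("turn_index must leave >= 2 samples on each side", call. = FALSE)
  }
  pre <- seq_len(turn_index - 1L)
  post <- turn_index:n
  s_pre <- drift_slope(series[pre], t[pre])
  s_post <- drift_slope(series[post], t[post])
  if (s_pre == 0) stop("zero pre-turn drift slope", call. = FALSE)
  100 * (abs(s_post) - abs(s_pre)) / abs(s_pre)
}

#' Bland-Altman agreement summary
#'
#' Mean of the paired differences `test - ref` and the 95% limits of
#' agreement, mean difference +/- 1.96 standard deviations of the
#' difference.
#'
#' @param test,ref equal-length numeric series, n >= 2.
#' @return list with `mean_diff`, `lo`, `hi`, `sd_diff`.
#' @export
bland_altman <- function(test, ref) {
  check_pair(test, ref, min_n = 2L)
  d <- test - ref
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, lo = m - 1.96 * s, hi = m + 1.96 * s, sd_diff = s)
}

#' One-sample t-test
#'
#' Two-sided Student t-test of the mean against `mu0` at significance
#' level `alpha`.
#'
#' @param values numeric sample, n >= 2, nonzero variance.
#' @param mu0 null mean (default 0).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `reject`.
#' @export
one_sample_ttest <- function(values, mu0 = 0, alpha = 0.05) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  ht <- stats::t.test(values, mu = mu0, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, reject = ht$p.value < alpha)
}

#' System Usability Scale scoring
#'
#' Standard SUS scoring of a 10-item, 5-point Likert questionnaire: odd
#' items contribute `response - 1`, even items contribute `5 - response`;
#' the per-user sum of contributions times 2.5 gives a 0-100 score, and
#' the mean over users summarizes the instrument.
#'
#' @param responses matrix or data frame with one row per user and 10
#'   integer columns in 1..5.
#' @return list with `scores` (per user) and `mean` (over users).
#' @export
sus_score <- function(responses) {
  responses <- as.matrix(responses)
  if (ncol(responses) != 10L) stop("expected 10 questionnaire items", call. = FALSE)
  if (any(responses != round(responses)) ||
      any(responses < 1) || any(responses > 5)) {
    stop("item scores must be integers in 1..5", call. = FALSE)
  }
  odd <- seq(1L, 9L, by = 2L)
  even <- seq(2L, 10L, by = 2L)
  contrib <- rowSums(responses[, odd, drop = FALSE] - 1) +
    rowSums(5 - responses[, even, drop = FALSE])
  scores <- 2.5 * contrib
  list(scores = scores, mean = mean(scores))
}

#' Full agreement report for a test-vs-reference signal pair
#'
#' Bundles the benchmarking suite: NRMSE, Pearson correlation, XApEn,
#' drift slopes of both signals and their ratio, Bland-Altman summary,
#' and (when a turn index is given) the turn drift increment of the test
#' signal.
#'
#' @param test,ref equal-length series, deg.
#' @param t time vector, s.
#' @param turn_index optional 1-based first post-turn sample index.
#' @param xapen_m,xapen_r XApEn parameters.
#' @param trim_s end-trim for the drift slopes, s.
#' @return an `agreement_report` list.
#' @export
agreement_report <- function(test, ref, t = seq_along(test) - 1,
                             turn_index = NULL, xapen_m = 2L, xapen_r = 0.2,
                             trim_s = 0) {
  ba <- bland_altman(test, ref)
  rep <- list(
    nrmse = nrmse(test, ref),
    rho = pearson_rho(test, ref),
    xapen = xapen(test, ref, m = xapen_m, r = xapen_r),
    drift_slope_test = drift_slope(test, t, trim_s = trim_s),
    drift_slope_ref = drift_slope(ref, t, trim_s = trim_s),
    ba_mean_diff = ba$mean_diff, ba_lo = ba$lo, ba_hi = ba$hi)
  rep$drift_ratio <- if (rep$drift_slope_ref != 0) {
    abs(rep$drift_slope_test) / abs(rep$drift_slope_ref)
  } else NA_real_
  if (!is.null(turn_index)) {
    rep$turn_drift_increment <- turn_drift_increment(test, t, turn_index)
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  NRMSE %.4f | rho %.4f | XApEn %.4f\n", x$nrmse, x$rho, x$xapen))
  cat(sprintf("  drift slope test %.5f ref %.5f deg/s (ratio %.2f)\n",
              x$drift_slope_test, x$drift_slope_ref, x$drift_ratio))
  cat(sprintf("  Bland-Altman %.3f [%.3f, %.3f] deg\n",
              x$ba_mean_diff, x$ba_lo, x$ba_hi))
  if (!is.null(x$turn_drift_increment)) {
    cat(sprintf("  turn drift increment %.1f%%\n", x$turn_drift_increment))
  }
  invisible(x)
}

check_pair <- function(test, ref, min_n = 1L) {
  if (length(test) != length(ref)) stop("series length mismatch", call. = FALSE)
  if (length(test) < min_n) stop("series too short", call. = FALSE)
  stopifnot_finite(test, "test"); stopifnot_finite(ref, "ref")
  invisible(NULL)
}
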