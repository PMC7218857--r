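#' Sagittal inclination from a quasi-static accelerometer sample
#'
#' Trigonometric accelerometer method: with the sensor at rest the
#' accelerometer reads the gravity unit vector, and the sagittal inclination
#' follows from its anterior (x) and vertical (z) components as
#' `atan2(ax, az)` in degrees. Used to initialize the fusion filters, which
#' cannot observe absolute orientation from angular rate alone.
#'
#' @param acc calibrated acceleration: length-3 vector or n-by-3 matrix, g.
#' @param min_norm reject samples whose norm is below this (free-fall or
#'   heavy motion makes the gravity direction unreliable).
#' @return inclination in degrees in `(-180, 180]`; a vector if `acc` is a
#'   matrix.
#' @export
accel_inclination <- function(acc, min_norm = 0.5) {
  if (is.null(dim(acc))) acc <- matrix(acc, nrow = 1L)
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("expected 3 accel axes", call. = FALSE)
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm < min_norm)) {
    stop("accelerometer norm below ", min_norm,
         " g: unreliable inclination", call. = FALSE)
  }
  ang <- rad2deg(atan2(acc[, 1L], acc[, 3L]))
  if (nrow(acc) == 1L) ang[[1L]] else ang
}

#' Fusion filter parameters
#'
#' Fixed complementary-filter gains (0.98 gyro / 0.02 accelerometer, chosen
#' as a trade-off between short-term gyro reliability and long-term
#' accelerometer reliability) and the Kalman process/measurement covariance
#' matrices.
#'
#' @param comp_gain_gyro gyroscope gain of the complementary filter; the
#'   accelerometer gain is its complement so the two sum to 1.
#' @param kalman_Q 2x2 process covariance for the (angle, gyro-bias) state.
#' @param kalman_R 2x2 measurement covariance for the (accelerometer angle,
#'   raw rate) measurement.
#' @param fs sampling frequency, Hz.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(comp_gain_gyro = 0.98,
                          kalman_Q = diag(c(0.005, 0.0003)),
                          kalman_R = diag(c(0.0669, 0.039)),
                          fs = 100) {
  if (comp_gain_gyro < 0 || comp_gain_gyro > 1) {
    stop("comp_gain_gyro must lie in [0, 1]", call. = FALSE)
  }
  check_psd <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m))) || any(eigen(m, symmetric = TRUE,
                                                 only.values = TRUE)$values < -1e-12)) {
      stop(what, " must be symmetric positive semi-definite", call. = FALSE)
    }
  }
  check_psd(kalman_Q, "kalman_Q"); check_psd(kalman_R, "kalman_R")
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(list(comp_gain_gyro = comp_gain_gyro,
                 comp_gain_acc = 1 - comp_gain_gyro,
                 kalman_Q = kalman_Q, kalman_R = kalman_R, fs = fs),
            class = "filter_params")
}

#' Complementary filter for sagittal segment orientation
#'
#' Fixed-gain recurrence fusing integrated angular rate with the
#' accelerometer inclination:
#' \deqn{\theta_k = 0.98\,(\theta_{k-1} + \omega_k / f_s) + 0.02\, a_k}
#' where \eqn{a_k} is the accelerometer-derived angle. The gyro path gives
#' short-term accuracy; the accelerometer path anchors the long-term mean
#' and bounds integration drift.
#'
#' @param gyro calibrated sagittal angular rate series, deg/s.
#' @param acc_angle accelerometer inclination series, deg, same length.
#' @param params a [filter_params()] (its `fs` and gains are used).
#' @param theta0 initial angle, deg, typically from [accel_inclination()].
#' @return angle series in degrees, same length as the input.
#' @export
complementary_filter <- function(gyro, acc_angle, params = filter_params(),
                                 theta0 = acc_angle[1L]) {
  n <- length(gyro)
  if (length(acc_angle) != n) stop("series length mismatch", call. = FALSE)
  stopifnot_finite(gyro, "gyro"); stopifnot_finite(acc_angle, "acc_angle")
  a <- params$comp_gain_gyro
  b <- params$comp_gain_acc
  dt <- 1 / params$fs
  theta <- numeric(n)
  prev <- theta0
  for (k in seq_len(n)) {
    prev <- a * (prev + gyro[k] * dt) + b * acc_angle[k]
    theta[k] <- prev
  }
  theta
}

#' Two-state Kalman filter for sagittal segment orientation
#'
#' Linear Kalman filter with state `(angle, gyro bias)`. The two measured
#' quantities are the accelerometer-derived angle and the raw angular rate.
#' The rate measurement drives the prediction as the control input,
#' `angle <- angle + (omega - bias)/fs`, with its variance (`R[2,2]`)
#' propagated into the state covariance through the integration step; the
#' accelerometer angle updates the state through the angle innovation,
#' weighted by `R[1,1]`. The bias state is observable through the
#' accumulated angle innovation (the classic two-state attitude filter),
#' so a constant rate bias is estimated and removed within seconds.
#' Covariances are the fixed 2x2 `Q` and `R` of [filter_params()].
#'
#' @inheritParams complementary_filter
#' @param P0 initial state covariance.
#' @return angle series in degrees with the estimated bias series attached
#'   as attribute `"bias"`.
#' @export
kalman_filter <- function(gyro, acc_angle, params = filter_params(),
                          theta0 = acc_angle[1L], P0 = diag(c(1, 1))) {
  n <- length(gyro)
  if (length(acc_angle) != n) stop("series length mismatch", call. = FALSE)
  stopifnot_finite(gyro, "gyro"); stopifnot_finite(acc_angle, "acc_angle")
  dt <- 1 / params$fs
  Q <- params$kalman_Q
  R <- params$kalman_R
  Fm <- matrix(c(1, 0, -dt, 1), 2L, 2L)
  B <- c(dt, 0)
  BRB <- (B %*% t(B)) * R[2L, 2L]   # rate-measurement noise through the integrator

  x <- c(theta0, 0)
  P <- P0
  theta <- numeric(n)
  bias <- numeric(n)
  for (k in seq_len(n)) {
    w <- gyro[k]
    x <- c(x[1L] + (w - x[2L]) * dt, x[2L])
    P <- Fm %*% P %*% t(Fm) + BRB + Q
    innov <- acc_angle[k] - x[1L]
    S <- P[1L, 1L] + R[1L, 1L]
    K <- P[, 1L] / S
    x <- x + K * innov
    P <- P - outer(K, P[1L, ])
    P <- (P + t(P)) / 2
    theta[k] <- x[1L]
    bias[k] <- x[2L]
  }
  attr(theta, "bias") <- bias
  theta
}

#' Integrate angular rate to an angle series
#'
#' Cumulative rectangular (Euler) integration at the sample interval, with
#' a trapezoidal option. Pure integration carries no attitude reference:
#' with a rate bias `b` the output drifts linearly at slope `b`, which makes
#' this the baseline against which the fusion filters and the drift metrics
#' are judged.
#'
#' @param gyro angular rate series, deg/s.
#' @param theta0 initial angle, deg (the value at the first sample).
#' @param fs sampling frequency, Hz.
#' @param method `"rectangular"` (default) or `"trapezoidal"`.
#' @return angle series, deg; `theta[1] == theta0`.
#' @export
integrate_gyro <- function(gyro, theta0, fs,
                           method = c("rectangular", "trapezoidal")) {
  method <- match.arg(method)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  stopifnot_finite(gyro, "gyro")
  n <- length(gyro)
  if (n == 0L) return(numeric(0))
  dt <- 1 / fs
  inc <- if (method == "rectangular") {
    gyro[-1L] * dt
  } else {
    (gyro[-1L] + gyro[-n]) / 2 * dt
  }
  theta0 + c(0, cumsum(inc))
}
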