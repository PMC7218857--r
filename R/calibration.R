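#' Static IMU calibration
#'
#' The calibration routine uses the first seconds of a trial, recorded while
#' the wearer stands still in N-pose, to estimate per-sensor correction
#' parameters: the gyroscope offset (mean scaled rate per axis) and the
#' accelerometer norm (Euclidean norm of the mean raw acceleration vector).
#' Scale factors are fixed by the sensor full-scale ranges: 0.06 deg/s per
#' count (gyro, +/-2000 deg/s) and 0.00024 g per count (accel, +/-8 g).
#' State starts at zero and is replaced — never blended — at each
#' calibration; no pre-defined parameters carry over between trials.
#'
#' @name calibration
NULL

#' Estimate the gyroscope offset from a static window
#'
#' Mean of the scaled gyroscope samples per axis over the static window.
#' The offset is computed on scaled values (counts times `gyro_scale`,
#' i.e. deg/s) so that subtracting it from scaled samples is
#' unit-consistent.
#'
#' @param static_counts n-by-3 matrix of raw gyroscope counts from the
#'   static prelude.
#' @param gyro_scale counts-to-deg/s factor.
#' @param check_static reject windows whose scaled per-axis standard
#'   deviation exceeds `max_sd` (the wearer moved during calibration).
#' @param max_sd static-posture validation threshold, deg/s.
#' @return length-3 numeric offset, deg/s.
#' @export
estimate_gyro_offset <- function(static_counts, gyro_scale = 0.06,
                                 check_static = TRUE, max_sd = 3) {
  static_counts <- as.matrix(static_counts)
  if (ncol(static_counts) != 3L) stop("expected 3 gyro axes", call. = FALSE)
  if (nrow(static_counts) < 2L) stop("too few static samples", call. = FALSE)
  stopifnot_finite(static_counts, "static gyro samples")
  scaled <- static_counts * gyro_scale
  if (check_static && any(apply(scaled, 2L, stats::sd) > max_sd)) {
    stop("calibration window not static: gyro sd exceeds ", max_sd,
         " deg/s", call. = FALSE)
  }
  colMeans(scaled)
}

#' Estimate the accelerometer norm from a static window
#'
#' Euclidean norm of the per-axis mean raw acceleration over the static
#' window, in counts: `sqrt(mean(ax)^2 + mean(ay)^2 + mean(az)^2)`.
#'
#' @param static_counts n-by-3 matrix of raw accelerometer counts.
#' @param check_static reject windows whose per-sample norm varies by more
#'   than `max_cv` (coefficient of variation) around its mean.
#' @param max_cv static-posture validation threshold (default 5%).
#' @return scalar norm in counts.
#' @export
estimate_acc_norm <- function(static_counts, check_static = TRUE, max_cv = 0.05) {
  static_counts <- as.matrix(static_counts)
  if (ncol(static_counts) != 3L) stop("expected 3 accel axes", call. = FALSE)
  if (nrow(static_counts) < 1L) stop("empty static window", call. = FALSE)
  stopifnot_finite(static_counts, "static accel samples")
  nrm <- sqrt(sum(colMeans(static_counts)^2))
  if (nrm <= 0) stop("zero accelerometer norm: sensor fault", call. = FALSE)
  if (check_static && nrow(static_counts) > 1L) {
    sample_norms <- sqrt(rowSums(static_counts^2))
    if (stats::sd(sample_norms) / mean(sample_norms) > max_cv) {
      stop("calibration window not static: accel norm varies > ",
           100 * max_cv, "%", call. = FALSE)
    }
  }
  nrm
}

#' Calibration state for one sensor
#'
#' @param gyro_offset length-3 offset, deg/s (zeros before calibration).
#' @param acc_norm accelerometer norm in counts (0 before calibration).
#' @param gyro_scale,acc_scale fixed scale factors.
#' @param window calibration window length, s.
#' @return an object of class `imu_calibration`.
#' @export
imu_calibration <- function(gyro_offset = c(0, 0, 0), acc_norm = 0,
                            gyro_scale = 0.06, acc_scale = 0.00024,
                            window = 10) {
  stopifnot(length(gyro_offset) == 3L, acc_norm >= 0)
  structure(list(gyro_offset = as.numeric(gyro_offset),
                 acc_norm = as.numeric(acc_norm),
                 gyro_scale = gyro_scale, acc_scale = acc_scale,
                 window = window),
            class = "imu_calibration")
}

#' @export
print.imu_calibration <- function(x, ...) {
  cat(sprintf("<imu_calibration> gyro offset [%s] deg/s, acc norm %.1f counts\n",
              paste(sprintf("%.3f", x$gyro_offset), collapse = ", "),
              x$acc_norm))
  invisible(x)
}

#' Apply gyroscope calibration
#'
#' `calibrated = raw * gyro_scale - offset`, per axis.
#'
#' @param raw_counts n-by-3 matrix (or length-3 vector) of raw counts.
#' @param state an [imu_calibration()] with an estimated offset.
#' @return calibrated angular rate, deg/s, same shape as the input.
#' @export
calibrate_gyro <- function(raw_counts, state) {
  stopifnot(inherits(state, "imu_calibration"))
  if (is.null(dim(raw_counts))) {
    raw_counts * state$gyro_scale - state$gyro_offset
  } else {
    sweep(as.matrix(raw_counts) * state$gyro_scale, 2L, state$gyro_offset)
  }
}

#' Apply accelerometer calibration
#'
#' Normalizes raw counts by the calibrated norm so that a static sensor
#' reads a unit (1 g) gravity vector: min-max normalization with bounds at
#' +/- the norm maps raw counts in `[-norm, +norm]` to `[-1, +1]`.
#'
#' @param raw_counts n-by-3 matrix (or length-3 vector) of raw counts.
#' @param state an [imu_calibration()] with `acc_norm > 0`.
#' @return calibrated acceleration in g, same shape as the input.
#' @export
calibrate_acc <- function(raw_counts, state) {
  stopifnot(inherits(state, "imu_calibration"))
  if (state$acc_norm <= 0) {
    stop("accelerometer norm not calibrated (zero)", call. = FALSE)
  }
  raw_counts / state$acc_norm
}

#' Calibrate every sensor of a trial from its static prelude
#'
#' @param trial an `imu_trial`.
#' @param window calibration window, s (default the trial's recorded
#'   prelude).
#' @param check_static validate that the window is truly static.
#' @return named list of [imu_calibration()] states, one per sensor id,
#'   with class `trial_calibration`.
#' @export
calibrate_trial <- function(trial, window = NULL, check_static = TRUE) {
  stopifnot(inherits(trial, "imu_trial"))
  fs <- attr(trial, "fs")
  if (is.null(window)) window <- attr(trial, "calib_window")
  params <- attr(trial, "params")
  gyro_scale <- if (!is.null(params)) params$gyro_scale else 0.06
  acc_scale <- if (!is.null(params)) params$acc_scale else 0.00024
  n_win <- round(window * fs)

  states <- list()
  for (id in unique(trial$sensor_id)) {
    rows <- trial[trial$sensor_id == id, , drop = FALSE]
    if (nrow(rows) < n_win) {
      stop(sprintf("sensor %s: fewer samples than the %g s window", id, window),
           call. = FALSE)
    }
    win <- rows[seq_len(n_win), , drop = FALSE]
    states[[id]] <- imu_calibration(
      gyro_offset = estimate_gyro_offset(win[, c("gx", "gy", "gz")],
                                         gyro_scale = gyro_scale,
                                         check_static = check_static),
      acc_norm = estimate_acc_norm(win[, c("ax", "ay", "az")],
                                   check_static = check_static),
      gyro_scale = gyro_scale, acc_scale = acc_scale, window = window)
  }
  structure(states, class = "trial_calibration")
}
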