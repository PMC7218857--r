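trial_columns <- c("sensor_id", "segment", "side", "t",
                   "gx", "gy", "gz", "ax", "ay", "az")

#' Write a raw IMU trial to delimited text
#'
#' One CSV row per sample per sensor with the mandatory header
#' `sensor_id,segment,side,t,gx,gy,gz,ax,ay,az`, plus a sidecar
#' `key: value` metadata file (sampling rate, calibration window, turn
#' index, seed, sensor parameters).
#'
#' @param trial an `imu_trial`.
#' @param path output CSV path.
#' @param meta_path sidecar metadata path; defaults to the CSV path with a
#'   `.yaml` extension.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, meta_path = NULL) {
  stopifnot(inherits(trial, "imu_trial"))
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.csv$", "", path), ".yaml")
  utils::write.csv(as.data.frame(trial)[, trial_columns], path, row.names = FALSE)
  params <- attr(trial, "params")
  meta <- list(fs = attr(trial, "fs"),
               calib_window = attr(trial, "calib_window"),
               turn_index = attr(trial, "turn_index"))
  if (!is.null(params)) meta$sensor <- unclass(params)
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}

#' Read a raw IMU trial from delimited text
#'
#' Validates the header, per-sensor strictly increasing uniform timestamps,
#' finite integer counts, and (against the configured sensor layout) the
#' completeness of the sensor set; missing sensors produce a warning, not
#' an error, since partial layouts still support some joints.
#'
#' @param path CSV path written by [write_trial()].
#' @param meta_path sidecar metadata path (default derived from `path`).
#' @param expected_segments segments the configured layout requires.
#' @return an `imu_trial`.
#' @export
read_trial <- function(path, meta_path = NULL,
                       expected_segments = c("trunk", "thigh", "shank", "foot")) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.csv$", "", path), ".yaml")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(colnames(df), trial_columns)) {
    stop("trial header does not match the expected schema", call. = FALSE)
  }
  num_cols <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  for (cc in num_cols) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column %s at data line %d", cc, bad[1L]),
           call. = FALSE)
    }
  }

  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  fs <- meta$fs
  for (id in unique(df$sensor_id)) {
    tt <- df$t[df$sensor_id == id]
    dts <- diff(tt)
    if (any(dts <= 0)) {
      stop(sprintf("sensor %s: timestamps not strictly increasing", id),
           call. = FALSE)
    }
    if (max(dts) - min(dts) > 1e-6) {
      stop(sprintf("sensor %s: non-uniform sampling", id), call. = FALSE)
    }
    if (is.null(fs)) fs <- 1 / stats::median(dts)
  }
  missing <- setdiff(expected_segments, unique(df$segment))
  if (length(missing)) {
    warning("trial missing segments: ", paste(missing, collapse = ", "),
            "; dependent joints cannot be computed", call. = FALSE)
  }
  params <- if (!is.null(meta$sensor)) do.call(sensor_params, meta$sensor) else NULL
  structure(df, class = c("imu_trial", "data.frame"),
            fs = fs,
            calib_window = if (!is.null(meta$calib_window)) meta$calib_window else 10,
            turn_index = if (!is.null(meta$turn_index)) meta$turn_index else NA_integer_,
            params = params)
}

#' Serialize / restore a trial calibration state
#'
#' Plain `key: value` text, one block per sensor.
#'
#' @param calib a `trial_calibration` from [calibrate_trial()].
#' @param path output path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "trial_calibration"))
  yaml::write_yaml(lapply(calib, unclass), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(lapply(raw, function(s) do.call(imu_calibration, s)),
            class = "trial_calibration")
}

#' Write / read a segment orientation table
#'
#' CSV with columns `t, segment, side, theta_deg`, long format.
#'
#' @param segments a [segment_series()].
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_series"))
  rows <- lapply(segment_streams(segments), function(s) {
    data.frame(t = segments$t, segment = s$segment, side = s$side,
               theta_deg = s$theta)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a joint-angle table
#'
#' CSV with columns
#' `t, side, hip_deg, knee_deg, ankle_deg, hip_vel, knee_vel, ankle_vel`.
#'
#' @param joints a [joint_series()].
#' @param path output path.
#' @export
write_joints <- function(joints, path) {
  stopifnot(inherits(joints, "joint_series"))
  vel <- joint_velocity(joints)
  rows <- lapply(colnames(joints$hip), function(side) {
    data.frame(t = joints$t, side = side,
               hip_deg = joints$hip[, side],
               knee_deg = joints$knee[, side],
               ankle_deg = joints$ankle[, side],
               hip_vel = vel$hip[, side],
               knee_vel = vel$knee[, side],
               ankle_vel = vel$ankle[, side])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
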