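#' Gait profile for the synthetic trajectory generator
#'
#' Describes a periodic sagittal-plane gait pattern as a per-joint harmonic
#' series. Each joint trajectory is
#' \deqn{\theta(t) = \mathrm{offset} + \sum_i A_i \sin(2\pi i f t + \phi_i)}
#' with stride frequency \eqn{f = \mathrm{cadence} / 120} Hz (a stride spans
#' two steps, so the stride period is \eqn{2 \cdot 60/\mathrm{cadence}} s).
#' Defaults emulate healthy adult walking: hip flexion/extension roughly
#' -10..30 deg, knee flexion 0..45 deg with its stance minimum at 0 deg,
#' ankle dorsi/plantarflexion roughly -15..15 deg. Terrain presets shift
#' offsets and amplitudes the way ramp and stair walking shift the sagittal
#' range of motion; speed presets set cadence and scale amplitudes slightly.
#'
#' @param terrain one of `"flat"`, `"ramp_ascend"`, `"ramp_descend"`,
#'   `"stair_ascend"`, `"stair_descend"`.
#' @param speed one of `"slow"`, `"normal"`, `"fast"`; sets the default
#'   cadence (90, 105, 120 steps/min) and an amplitude scale (0.9, 1, 1.1).
#' @param n_cycles number of strides to generate (>= 1).
#' @param cadence steps per minute; overrides the speed preset when given.
#' @param harmonics optional named list (`hip`, `knee`, `ankle`), each a list
#'   with numeric `offset`, `amp` and `phase` (phase in radians, one entry
#'   per harmonic). Overrides the terrain/speed presets entirely.
#' @param trunk_lean constant forward trunk lean in degrees added to the
#'   neutral 90 deg trunk orientation.
#' @return an object of class `gait_profile`.
#' @seealso [generate_joint_trajectories()], [sensor_params()]
#' @export
gait_profile <- function(terrain = c("flat", "ramp_ascend", "ramp_descend",
                                     "stair_ascend", "stair_descend"),
                         speed = c("normal", "slow", "fast"),
                         n_cycles = 10L,
                         cadence = NULL,
                         harmonics = NULL,
                         trunk_lean = 2) {
  terrain <- match.arg(terrain)
  speed <- match.arg(speed)
  if (is.null(cadence)) {
    cadence <- switch(speed, slow = 90, normal = 105, fast = 120)
  }
  if (!is.numeric(cadence) || length(cadence) != 1L || cadence <= 0) {
    stop("cadence must be a single positive number (steps/min)", call. = FALSE)
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)

  if (is.null(harmonics)) {
    harmonics <- default_harmonics(terrain, speed)
  }
  for (j in c("hip", "knee", "ankle")) {
    h <- harmonics[[j]]
    if (is.null(h)) stop(sprintf("harmonics missing joint '%s'", j), call. = FALSE)
    if (length(h$amp) != length(h$phase)) {
      stop("amp and phase must have equal length per joint", call. = FALSE)
    }
    stopifnot_finite(c(h$offset, h$amp, h$phase), sprintf("%s harmonics", j))
  }

  structure(
    list(terrain = terrain, speed_label = speed, cadence = cadence,
         n_cycles = as.integer(n_cycles), harmonics = harmonics,
         trunk_lean = trunk_lean),
    class = "gait_profile"
  )
}

# terrain/speed presets for the per-joint harmonic series; amplitudes in
# degrees, phases in radians relative to the stride cycle
default_harmonics <- function(terrain, speed) {
  # flat walking base pattern; knee written so its stance minimum is exactly 0
  h <- list(
    hip   = list(offset = 10, amp = c(20),     phase = c(0)),
    knee  = list(offset = 30, amp = c(20, 10), phase = c(-pi / 2, -pi / 2)),
    ankle = list(offset = 0,  amp = c(10, 5),  phase = c(0, -pi / 2))
  )
  if (terrain == "ramp_ascend") {
    h$hip$offset <- h$hip$offset + 8
    h$ankle$offset <- h$ankle$offset + 4
  } else if (terrain == "ramp_descend") {
    h$hip$offset <- h$hip$offset - 4
    h$knee$offset <- h$knee$offset + 5
  } else if (terrain == "stair_ascend") {
    h$hip$offset <- h$hip$offset + 15
    h$knee$amp[1] <- h$knee$amp[1] + 15
  } else if (terrain == "stair_descend") {
    h$knee$amp[1] <- h$knee$amp[1] + 10
    h$ankle$amp[1] <- h$ankle$amp[1] + 5
  }
  scale <- switch(speed, slow = 0.9, normal = 1, fast = 1.1)
  for (j in names(h)) h[[j]]$amp <- h[[j]]$amp * scale
  h
}

#' IMU sensor model parameters
#'
#' Parameters of the synthetic MEMS signal chain: additive gyroscope bias and
#' white noise, accelerometer white noise, the fixed count-to-physical scale
#' factors (0.06 deg/s per count for a +/-2000 deg/s gyroscope, 0.00024 g per
#' count for a +/-8 g accelerometer), and a slow orientation drift injected as
#' a constant angular-rate offset (deg/s) switched on after the static
#' calibration prelude, so the integrated angle drifts linearly at
#' `drift_slope`.
#'
#' @param fs sampling frequency in Hz, integer in 1..200.
#' @param gyro_noise_sd gyroscope white-noise standard deviation, deg/s.
#' @param gyro_bias length-3 constant gyroscope bias, deg/s per axis.
#' @param acc_noise_sd accelerometer white-noise standard deviation, g.
#' @param gyro_scale counts-to-deg/s factor (default 0.06).
#' @param acc_scale counts-to-g factor (default 0.00024).
#' @param drift_slope injected orientation drift, deg/s (0 disables).
#' @param seed integer RNG seed; the same seed gives bit-identical trials.
#' @return an object of class `sensor_params`.
#' @export
sensor_params <- function(fs = 100L,
                          gyro_noise_sd = 0.5,
                          gyro_bias = c(0, 0, 0),
                          acc_noise_sd = 0.01,
                          gyro_scale = 0.06,
                          acc_scale = 0.00024,
                          drift_slope = 0,
                          seed = 1L) {
  fs <- as.integer(fs)
  if (is.na(fs) || fs < 1L || fs > 200L) {
    stop("fs must be an integer in 1..200 Hz", call. = FALSE)
  }
  if (gyro_scale <= 0 || acc_scale <= 0) stop("scale factors must be > 0", call. = FALSE)
  if (length(gyro_bias) != 3L) stop("gyro_bias must have length 3", call. = FALSE)
  structure(
    list(fs = fs, gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
         acc_noise_sd = acc_noise_sd, gyro_scale = gyro_scale,
         acc_scale = acc_scale, drift_slope = drift_slope,
         seed = as.integer(seed)),
    class = "sensor_params"
  )
}

#' Construct a joint-angle series
#'
#' Container for sagittal hip/knee/ankle angle series (degrees). Each joint
#' is an n-by-k matrix whose columns are sides (typically `"left"`,
#' `"right"`).
#'
#' @param hip,knee,ankle numeric matrices (or vectors, taken as one side)
#'   with identical dimensions, degrees.
#' @param fs sampling frequency, Hz.
#' @param t optional time vector, seconds; defaults to `(0:(n-1))/fs`.
#' @return an object of class `joint_series`.
#' @export
joint_series <- function(hip, knee, ankle, fs, t = NULL) {
  as_side_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L, dimnames = list(NULL, "right"))
  }
  hip <- as_side_matrix(hip); knee <- as_side_matrix(knee); ankle <- as_side_matrix(ankle)
  if (!identical(dim(hip), dim(knee)) || !identical(dim(hip), dim(ankle))) {
    stop("hip, knee, ankle must share dimensions", call. = FALSE)
  }
  n <- nrow(hip)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  if (length(t) != n) stop("time vector length mismatch", call. = FALSE)
  structure(list(t = t, fs = fs, hip = hip, knee = knee, ankle = ankle),
            class = "joint_series")
}

#' @export
print.joint_series <- function(x, ...) {
  cat(sprintf("<joint_series> %d samples @ %g Hz (%.2f s), sides: %s\n",
              nrow(x$hip), x$fs, nrow(x$hip) / x$fs,
              paste(colnames(x$hip), collapse = ", ")))
  invisible(x)
}

#' Construct a segment-orientation series
#'
#' Sagittal inclination series (degrees) per body segment. The trunk is a
#' single shared series; thigh, shank and foot are n-by-k matrices with one
#' column per side. Neutral stance convention: trunk 90, thigh -90,
#' shank -90, foot 0 deg (the unique values under which the trigonometric
#' joint computation yields zero joint angles while standing).
#'
#' @param trunk numeric vector, degrees.
#' @param thigh,shank,foot matrices (or vectors) with matching rows.
#' @param fs sampling frequency, Hz.
#' @param t optional time vector, seconds.
#' @return an object of class `segment_series`.
#' @export
segment_series <- function(trunk, thigh, shank, foot, fs, t = NULL) {
  as_side_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L, dimnames = list(NULL, "right"))
  }
  thigh <- as_side_matrix(thigh); shank <- as_side_matrix(shank); foot <- as_side_matrix(foot)
  n <- length(trunk)
  if (nrow(thigh) != n || nrow(shank) != n || nrow(foot) != n) {
    stop("segment series must share length", call. = FALSE)
  }
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  structure(list(t = t, fs = fs, trunk = trunk, thigh = thigh,
                 shank = shank, foot = foot),
            class = "segment_series")
}

#' @export
print.segment_series <- function(x, ...) {
  cat(sprintf("<segment_series> %d samples @ %g Hz, sides: %s\n",
              length(x$trunk), x$fs, paste(colnames(x$thigh), collapse = ", ")))
  invisible(x)
}

#' Generate ground-truth joint trajectories for a gait profile
#'
#' Evaluates the profile's harmonic series on a uniform time grid covering
#' `n_cycles` strides at the requested sampling rate. Both sides are
#' produced; the left side lags the right by half a stride, as in symmetric
#' gait.
#'
#' @param profile a [gait_profile()].
#' @param fs sampling frequency, Hz (or a [sensor_params()], whose `fs` is
#'   used).
#' @return a [joint_series()] with `left` and `right` columns per joint.
#' @examples
#' js <- generate_joint_trajectories(gait_profile(n_cycles = 2), fs = 100)
#' range(js$knee[, "right"])
#' @export
generate_joint_trajectories <- function(profile, fs = 100) {
  stopifnot(inherits(profile, "gait_profile"))
  if (inherits(fs, "sensor_params")) fs <- fs$fs
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  stride_period <- 2 * 60 / profile$cadence
  n <- max(2L, round(profile$n_cycles * stride_period * fs))
  t <- (seq_len(n) - 1L) / fs
  f <- 1 / stride_period

  eval_joint <- function(h, phase_shift) {
    th <- rep(h$offset, n)
    for (i in seq_along(h$amp)) {
      th <- th + h$amp[i] * sin(2 * pi * i * f * t + h$phase[i] + i * phase_shift)
    }
    th
  }
  side_mat <- function(h) {
    cbind(left = eval_joint(h, pi), right = eval_joint(h, 0))
  }
  joint_series(hip = side_mat(profile$harmonics$hip),
               knee = side_mat(profile$harmonics$knee),
               ankle = side_mat(profile$harmonics$ankle),
               fs = fs, t = t)
}

#' Convert joint angles to segment orientations
#'
#' Algebraic inversion of the trigonometric joint-angle relations: given
#' hip/knee/ankle angles and a trunk orientation series, returns the unique
#' segment orientations satisfying
#' \deqn{\theta_{Thigh} = \theta_{Trunk} - 180 + \theta_{Hip}}
#' \deqn{\theta_{Shank} = \theta_{Thigh} - \theta_{Knee}}
#' \deqn{\theta_{Foot}  = \theta_{Ankle} + 90 + \theta_{Shank}}
#' so that [joint_angles()] applied to the result recovers the inputs.
#'
#' @param joints a [joint_series()].
#' @param trunk trunk orientation series, degrees; a scalar is recycled.
#'   Defaults to 90 deg (neutral upright trunk).
#' @return a [segment_series()].
#' @export
joints_to_segments <- function(joints, trunk = 90) {
  stopifnot(inherits(joints, "joint_series"))
  n <- nrow(joints$hip)
  if (length(trunk) == 1L) trunk <- rep(trunk, n)
  if (length(trunk) != n) stop("trunk series length mismatch", call. = FALSE)
  thigh <- trunk - 180 + joints$hip
  shank <- thigh - joints$knee
  foot <- joints$ankle + 90 + shank
  segment_series(trunk = trunk, thigh = thigh, shank = shank, foot = foot,
                 fs = joints$fs, t = joints$t)
}

#' Synthesize a raw multi-IMU trial from segment orientations
#'
#' Models the signal chain of a body-worn MEMS IMU network: one sensor per
#' segment/side (up to 7: trunk plus left/right thigh, shank, foot). For
#' each sensor the sagittal angular rate (backward difference of the segment
#' angle) plus bias, white noise and the post-prelude drift-rate offset is
#' scaled to gyroscope counts on the mediolateral axis (y); off-plane gyro
#' axes carry bias and noise only. The accelerometer measures the gravity
#' unit vector rotated into the sensor frame (anterior x, vertical z) plus
#' white noise, scaled to counts. Counts are quantized by rounding half away
#' from zero and saturated at +/-32767. A 10-second static prelude at the
#' initial pose is prepended for calibration.
#'
#' @param segments a [segment_series()] at the sensor sampling rate.
#' @param sensor a [sensor_params()].
#' @param calib_window static prelude duration prepended before motion, s.
#' @return an `imu_trial`: a data frame with columns
#'   `sensor_id, segment, side, t, gx, gy, gz, ax, ay, az` (counts) and
#'   attributes `fs`, `calib_window`, `turn_index`, `params`.
#' @export
synthesize_imu <- function(segments, sensor, calib_window = 10) {
  stopifnot(inherits(segments, "segment_series"), inherits(sensor, "sensor_params"))
  if (!isTRUE(all.equal(segments$fs, sensor$fs))) {
    stop("segment series fs does not match sensor fs", call. = FALSE)
  }
  fs <- sensor$fs
  n_pre <- round(calib_window * fs)

  streams <- segment_streams(segments)
  for (s in streams) stopifnot_finite(s$theta, "segment angle series")

  set.seed(sensor$seed)
  rows <- lapply(streams, function(s) {
    theta_full <- c(rep(s$theta[1L], n_pre), s$theta)
    n_tot <- length(theta_full)
    # backward-difference rate, consistent with rectangular integration
    omega <- c(0, diff(theta_full)) * fs
    drift <- sensor$drift_slope * (seq_len(n_tot) > n_pre)
    gy <- omega + sensor$gyro_bias[2L] + drift +
      rnorm(n_tot, sd = sensor$gyro_noise_sd)
    gx <- sensor$gyro_bias[1L] + rnorm(n_tot, sd = sensor$gyro_noise_sd)
    gz <- sensor$gyro_bias[3L] + rnorm(n_tot, sd = sensor$gyro_noise_sd)
    ax <- sind(theta_full) + rnorm(n_tot, sd = sensor$acc_noise_sd)
    ay <- rnorm(n_tot, sd = sensor$acc_noise_sd)
    az <- cosd(theta_full) + rnorm(n_tot, sd = sensor$acc_noise_sd)
    data.frame(
      sensor_id = s$id, segment = s$segment, side = s$side,
      t = (seq_len(n_tot) - 1L) / fs,
      gx = quantize_counts(gx / sensor$gyro_scale),
      gy = quantize_counts(gy / sensor$gyro_scale),
      gz = quantize_counts(gz / sensor$gyro_scale),
      ax = quantize_counts(ax / sensor$acc_scale),
      ay = quantize_counts(ay / sensor$acc_scale),
      az = quantize_counts(az / sensor$acc_scale),
      stringsAsFactors = FALSE
    )
  })
  trial <- do.call(rbind, rows)
  rownames(trial) <- NULL
  structure(trial,
            class = c("imu_trial", "data.frame"),
            fs = fs, calib_window = calib_window,
            turn_index = NA_integer_, params = sensor)
}

# flatten a segment_series into per-sensor streams
segment_streams <- function(segments) {
  out <- list(list(id = "trunk_c", segment = "trunk", side = "center",
                   theta = segments$trunk))
  for (seg in c("thigh", "shank", "foot")) {
    m <- segments[[seg]]
    for (side in colnames(m)) {
      out[[length(out) + 1L]] <- list(
        id = paste(seg, substr(side, 1L, 1L), sep = "_"),
        segment = seg, side = side, theta = m[, side])
    }
  }
  out
}

#' @export
print.imu_trial <- function(x, ...) {
  ids <- unique(x$sensor_id)
  cat(sprintf(
    "<imu_trial> %d sensors x %d samples @ %g Hz (%.1f s incl. %g s static prelude)\n",
    length(ids), sum(x$sensor_id == ids[1L]), attr(x, "fs"),
    max(x$t), attr(x, "calib_window")))
  if (!is.na(attr(x, "turn_index"))) {
    cat(sprintf("  180-deg turn at sample %d\n", attr(x, "turn_index")))
  }
  invisible(x)
}

#' Inject a 180-degree turn event into a trial
#'
#' Marks the turn and multiplies the injected drift rate for all samples at
#' or after the turn, emulating the drift amplification observed when a
#' walker reverses direction. The added counts are accumulated through an
#' error-diffusion quantizer so the integrated post-turn drift slope is
#' exactly `multiplier * drift_slope` up to one count.
#'
#' @param trial an `imu_trial` produced by [synthesize_imu()].
#' @param at turn time, s, within `[0, max(t)]`.
#' @param multiplier post-turn drift-slope multiplier (1 leaves the trial
#'   unchanged apart from the turn marker).
#' @return the modified `imu_trial` with attribute `turn_index` set (1-based
#'   per-sensor sample index of the first post-turn sample).
#' @export
inject_turn <- function(trial, at, multiplier = 2) {
  stopifnot(inherits(trial, "imu_trial"))
  fs <- attr(trial, "fs")
  params <- attr(trial, "params")
  t_max <- max(trial$t)
  if (!is.numeric(at) || length(at) != 1L || at < 0 || at > t_max) {
    stop("turn time 'at' outside trial duration", call. = FALSE)
  }
  turn_index <- as.integer(floor(at * fs)) + 1L
  delta_rate <- (multiplier - 1) * params$drift_slope

  if (delta_rate != 0) {
    per_sensor_n <- sum(trial$sensor_id == trial$sensor_id[1L])
    k_post <- seq_len(max(0L, per_sensor_n - turn_index + 1L))
    target <- delta_rate * k_post / params$gyro_scale
    add <- as.integer(diff(c(0, round(target))))
    for (id in unique(trial$sensor_id)) {
      idx <- which(trial$sensor_id == id)
      post <- idx[turn_index:per_sensor_n]
      trial$gy[post] <- trial$gy[post] + add
    }
  }
  attr(trial, "turn_index") <- turn_index
  attr(trial, "turn_multiplier") <- multiplier
  trial
}
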