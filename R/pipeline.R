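#' Estimate segment orientations for every sensor of a trial
#'
#' Runs the chosen fusion method per sensor on the calibrated motion
#' samples (everything after the static calibration window). The filter is
#' initialized from the mean accelerometer inclination over the static
#' window; per-sample accelerometer angles drive the correction term.
#' Outputs are wrapped into the segment range conventions (leg segments
#' `[-270, 180]`, trunk `[-180, 180]`).
#'
#' @param trial an `imu_trial`.
#' @param calib a `trial_calibration` from [calibrate_trial()].
#' @param method `"complementary"`, `"kalman"` or `"integration"` (pure
#'   gyro integration, the drifting baseline).
#' @param params a [filter_params()]; its `fs` is overridden by the
#'   trial's sampling rate.
#' @return a [segment_series()] over the motion samples. If a segment has
#'   no sensor the series is built without it and joint computations that
#'   need it will refuse.
#' @export
fuse_trial <- function(trial, calib,
                       method = c("complementary", "kalman", "integration"),
                       params = filter_params()) {
  method <- match.arg(method)
  stopifnot(inherits(trial, "imu_trial"), inherits(calib, "trial_calibration"))
  fs <- attr(trial, "fs")
  params$fs <- fs
  n_pre <- round(attr(trial, "calib_window") * fs)

  est <- list()
  t_motion <- NULL
  for (id in unique(trial$sensor_id)) {
    rows <- trial[trial$sensor_id == id, , drop = FALSE]
    state <- calib[[id]]
    if (is.null(state)) stop("no calibration state for sensor ", id, call. = FALSE)
    gyro <- calibrate_gyro(as.matrix(rows[, c("gx", "gy", "gz")]), state)
    acc <- calibrate_acc(as.matrix(rows[, c("ax", "ay", "az")]), state)
    theta0 <- accel_inclination(colMeans(acc[seq_len(n_pre), , drop = FALSE]))
    motion <- (n_pre + 1L):nrow(rows)
    w <- gyro[motion, 2L]                       # sagittal rate: mediolateral axis
    acc_angle <- accel_inclination(acc[motion, , drop = FALSE])
    theta <- switch(method,
      complementary = complementary_filter(w, acc_angle, params, theta0),
      kalman = as.numeric(kalman_filter(w, acc_angle, params, theta0)),
      integration = integrate_gyro(w, theta0, fs))
    seg <- rows$segment[1L]
    kind <- if (seg == "trunk") "other" else "leg"
    est[[id]] <- list(segment = seg, side = rows$side[1L],
                      theta = wrap_segment(theta, kind))
    if (is.null(t_motion)) t_motion <- rows$t[motion]
  }

  seg_of <- vapply(est, `[[`, "", "segment")
  pick <- function(seg) {
    hits <- est[seg_of == seg]
    if (!length(hits)) return(NULL)
    m <- do.call(cbind, lapply(hits, `[[`, "theta"))
    colnames(m) <- vapply(hits, `[[`, "", "side")
    m[, order(colnames(m)), drop = FALSE]
  }
  trunk_m <- pick("trunk")
  if (is.null(trunk_m)) stop("trial has no trunk sensor", call. = FALSE)
  out <- list(t = t_motion, fs = fs, trunk = trunk_m[, 1L],
              thigh = pick("thigh"), shank = pick("shank"), foot = pick("foot"))
  structure(out[!vapply(out, is.null, TRUE)], class = "segment_series")
}

#' Pipeline configuration
#'
#' Settings for the end-to-end run: simulate (or read) a trial, calibrate,
#' fuse, compute joint angles, optionally train and apply drift
#' correction, and benchmark against the reference.
#'
#' @param seed master seed; all randomness in the run derives from it.
#' @param fs sampling frequency, Hz (<= 200).
#' @param method fusion method (see [fuse_trial()]).
#' @param terrain,speed,n_cycles simulated gait condition.
#' @param sensor a [sensor_params()]; its `fs`/`seed` are overridden by
#'   the pipeline's.
#' @param trial_csv optional path to an existing trial; skips simulation
#'   (no ground-truth reference is then available).
#' @param correction `NULL`, or a [regression_spec()] to train per-joint
#'   drift correction against the reference.
#' @param xapen_m,xapen_r XApEn parameters for the report.
#' @param out_dir output directory for the CSV/YAML artifacts; `NULL`
#'   disables writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, fs = 100L,
                            method = "complementary",
                            terrain = "flat", speed = "normal", n_cycles = 10L,
                            sensor = sensor_params(),
                            trial_csv = NULL,
                            correction = NULL,
                            xapen_m = 2L, xapen_r = 0.2,
                            out_dir = NULL) {
  if (fs > 200) stop("fs must be <= 200 Hz", call. = FALSE)
  structure(list(seed = as.integer(seed), fs = as.integer(fs), method = method,
                 terrain = terrain, speed = speed, n_cycles = n_cycles,
                 sensor = sensor, trial_csv = trial_csv,
                 correction = correction,
                 xapen_m = xapen_m, xapen_r = xapen_r, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full processing pipeline
#'
#' simulate/load -> calibrate (static window) -> fuse -> joint angles ->
#' optional regression correction -> agreement metrics. Fully
#' deterministic for a fixed configuration: two runs produce byte-identical
#' output files.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the trial, calibration, segment and
#'   joint series, corrected joints (if requested), per-joint
#'   [agreement_report()]s against the simulator ground truth (when
#'   simulated), and the paths of any files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$trial_csv)) {
    sensor <- config$sensor
    sensor$fs <- config$fs
    sensor$seed <- config$seed
    profile <- gait_profile(terrain = config$terrain, speed = config$speed,
                            n_cycles = config$n_cycles)
    truth <- generate_joint_trajectories(profile, fs = config$fs)
    true_segments <- joints_to_segments(truth, trunk = 90 + profile$trunk_lean)
    trial <- stage("simulate", synthesize_imu(true_segments, sensor))
  } else {
    trial <- stage("read", read_trial(config$trial_csv))
  }

  message("calibration: estimating offsets from the static window")
  calib <- stage("calibrate", calibrate_trial(trial))
  message("acquisition: fusing segment orientations (", config$method, ")")
  segments <- stage("fuse",
    fuse_trial(trial, calib, method = config$method,
               params = filter_params(fs = attr(trial, "fs"))))
  joints <- stage("joints", joint_angles(segments))
  vel <- joint_velocity(joints)

  corrected <- NULL
  models <- NULL
  if (!is.null(config$correction)) {
    if (is.null(truth)) stop("[correct] correction needs a reference", call. = FALSE)
    corrected <- joints
    models <- list()
    for (j in c("hip", "knee", "ankle")) {
      for (side in colnames(joints[[j]])) {
        spec <- config$correction
        spec$seed <- config$seed
        m <- stage("correct",
          fit_drift_model(joints[[j]][, side], truth[[j]][, side],
                          velocity = vel[[j]][, side], spec = spec))
        corrected[[j]][, side] <-
          apply_correction(m, joints[[j]][, side], vel[[j]][, side])
        models[[paste(j, side, sep = "_")]] <- m
      }
    }
  }

  reports <- NULL
  if (!is.null(truth)) {
    use <- if (is.null(corrected)) joints else corrected
    reports <- list()
    for (j in c("hip", "knee", "ankle")) {
      reports[[j]] <- stage("benchmark",
        agreement_report(use[[j]][, "right"], truth[[j]][, "right"],
                         t = use$t, xapen_m = config$xapen_m,
                         xapen_r = config$xapen_r))
    }
  }

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_trial(trial, p("trial.csv"))
    write_calibration(calib, p("calib.yaml"))
    write_segments(segments, p("segments.csv"))
    write_joints(joints, p("joints.csv"))
    paths <- c(p("trial.csv"), p("trial.yaml"), p("calib.yaml"),
               p("segments.csv"), p("joints.csv"))
    if (!is.null(corrected)) {
      write_joints(corrected, p("corrected.csv"))
      paths <- c(paths, p("corrected.csv"))
    }
    if (!is.null(reports)) {
      yaml::write_yaml(lapply(reports, unclass), p("report.yaml"))
      paths <- c(paths, p("report.yaml"))
    }
  }

  invisible(list(trial = trial, calibration = calib, segments = segments,
                 joints = joints, velocity = vel, corrected = corrected,
                 models = models, truth = truth, reports = reports,
                 paths = paths))
}
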