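#' Wrap a segment angle into its range convention
#'
#' Leg segments (thigh, shank, foot) live in `[-270, 180]` degrees; the
#' trunk and all joint angles live in `[-180, 180]`. Values already inside
#' the range are returned unchanged; values outside are brought in by
#' 360-degree shifts, so the map is idempotent.
#'
#' @param theta angle(s), degrees, finite.
#' @param kind `"leg"` or `"other"`.
#' @return wrapped angle(s), degrees.
#' @examples
#' wrap_segment(185, "leg")    # -175
#' wrap_segment(-181, "other") # 179
#' @export
wrap_segment <- function(theta, kind = c("other", "leg")) {
  kind <- match.arg(kind)
  stopifnot_finite(theta, "theta")
  lo <- if (kind == "leg") -270 else -180
  hi <- 180
  up <- theta > hi
  theta[up] <- theta[up] - 360 * ceiling((theta[up] - hi) / 360)
  dn <- theta < lo
  theta[dn] <- theta[dn] + 360 * ceiling((lo - theta[dn]) / 360)
  theta
}

#' Sagittal joint angles from segment orientations
#'
#' Trigonometric joint-angle relations in the segment convention where
#' neutral upright stance is trunk 90, thigh -90, shank -90, foot 0 deg:
#' \deqn{\theta_{Ankle} = -90 - \theta_{Shank} + \theta_{Foot}}
#' \deqn{\theta_{Knee}  = \theta_{Thigh} - \theta_{Shank}}
#' \deqn{\theta_{Hip}   = -(\theta_{Trunk} - \theta_{Thigh} - 180)}
#' Results are wrapped to `[-180, 180]`. The relations are affine, so they
#' commute with consistent 360-degree shifts of the segment inputs.
#'
#' @param segments a [segment_series()] with all four segments.
#' @return a [joint_series()] (no velocity channel; see
#'   [joint_velocity()]).
#' @export
joint_angles <- function(segments) {
  stopifnot(inherits(segments, "segment_series"))
  for (f in c("trunk", "thigh", "shank", "foot")) {
    if (is.null(segments[[f]])) stop("missing segment: ", f, call. = FALSE)
  }
  ankle <- -90 - segments$shank + segments$foot
  knee <- segments$thigh - segments$shank
  hip <- -(segments$trunk - segments$thigh - 180)
  joint_series(hip = wrap_segment(hip, "other"),
               knee = wrap_segment(knee, "other"),
               ankle = wrap_segment(ankle, "other"),
               fs = segments$fs, t = segments$t)
}

#' Joint angular velocity by finite differences
#'
#' Central differences in the interior, one-sided at the ends, scaled by the
#' sampling rate. Second-order accurate in the interior.
#'
#' @param x angle series, degrees: numeric vector or matrix (columns
#'   differentiated independently), or a [joint_series()] (every joint and
#'   side differentiated; returns a named list of matrices).
#' @param fs sampling frequency, Hz.
#' @return velocity in deg/s, same shape as the input.
#' @export
joint_velocity <- function(x, fs) {
  if (inherits(x, "joint_series")) {
    return(lapply(x[c("hip", "knee", "ankle")], joint_velocity, fs = x$fs))
  }
  if (is.matrix(x)) return(apply(x, 2L, joint_velocity, fs = fs))
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) {
    k <- 2:(n - 1L)
    v[k] <- (x[k + 1L] - x[k - 1L]) * fs / 2
  }
  v
}
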