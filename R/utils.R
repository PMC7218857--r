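# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

sind <- function(x) sin(deg2rad(x))
cosd <- function(x) cos(deg2rad(x))

# round half away from zero: emulates a symmetric ADC quantizer without
# the even-rounding bias of base round()
quantize_counts <- function(x, full_scale = 32767L) {
  q <- sign(x) * floor(abs(x) + 0.5)
  q <- pmax(pmin(q, full_scale), -full_scale)
  as.integer(q)
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# ordinary least-squares slope of y against t (closed form)
ols_slope <- function(y, t) {
  tc <- t - mean(t)
  den <- sum(tc^2)
  if (den <= 0) stop("degenerate time vector: zero variance", call. = FALSE)
  sum(tc * (y - mean(y))) / den
}
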