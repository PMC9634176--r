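#' Interpolate missing samples by cubic spline
#'
#' Fills gaps in each axis independently with a cubic spline through the
#' known samples (the FMM scheme of [stats::splinefun()], which reproduces
#' cubic polynomials exactly). Leading and trailing missing runs are filled
#' by nearest-known-value extension: cubic extrapolation is unstable and the
#' session start/end never enters any analysis window. Non-missing samples
#' are returned bit-for-bit unchanged.
#'
#' @param s an [accel_ts()].
#' @return An [accel_ts()] with an all-`FALSE` missing mask.
#' @export
interpolate_missing <- function(s) {
  stopifnot(inherits(s, "accel_ts"))
  if (!any(s$missing)) return(s)
  known <- !s$missing
  if (sum(known) < 4)
    stop("cubic spline interpolation needs at least 4 non-missing samples")
  fill_axis <- function(v) {
    f <- stats::splinefun(s$t[known], v[known], method = "fmm")
    miss <- which(s$missing)
    first_k <- s$t[which(known)[1]]
    last_k <- s$t[which(known)[sum(known)]]
    out <- v
    interior <- miss[s$t[miss] > first_k & s$t[miss] < last_k]
    out[interior] <- f(s$t[interior])
    out[miss[s$t[miss] <= first_k]] <- v[which(known)[1]]
    out[miss[s$t[miss] >= last_k]] <- v[which(known)[sum(known)]]
    out
  }
  accel_ts(s$t, fill_axis(s$ax), fill_axis(s$ay), fill_axis(s$az), s$fs)
}

#' Collapse tri-axial acceleration to its Euclidean magnitude
#'
#' The normalized acceleration `Acc(t) = sqrt(ax(t)^2 + ay(t)^2 + az(t)^2)`,
#' the one-dimensional series all downstream detection and coherence stages
#' work on. Requires a gap-free series; run [interpolate_missing()] first.
#'
#' @param s an [accel_ts()] without missing samples.
#' @return A [magnitude_series()] with provenance `"RAW_NORM"`.
#' @export
magnitude <- function(s) {
  stopifnot(inherits(s, "accel_ts"))
  if (any(s$missing))
    stop("series has missing samples; run interpolate_missing() first")
  magnitude_series(s$t, sqrt(s$ax^2 + s$ay^2 + s$az^2), s$fs, "RAW_NORM")
}

#' Third-order median filter
#'
#' Replaces each value with the median of itself and its two neighbours,
#' removing one-point outliers. Edges are zero-padded (the convention of the
#' reference routine this mirrors), so `out[1] = median(0, x[1], x[2])` and
#' symmetrically at the end.
#'
#' @param m a [magnitude_series()] of length at least 3.
#' @return A [magnitude_series()] with provenance `"SMOOTHED"`.
#' @export
median_smooth <- function(m) {
  stopifnot(inherits(m, "magnitude_series"))
  x <- m$acc
  n <- length(x)
  if (n < 3) stop("median filter needs at least 3 samples")
  left <- c(0, x[-n])
  right <- c(x[-1], 0)
  out <- left + x + right - pmax(left, x, right) - pmin(left, x, right)
  magnitude_series(m$t, out, m$fs, "SMOOTHED")
}

#' Full pre-processing chain for one sensor
#'
#' Fixed order: spline interpolation of missing samples, Euclidean
#' magnitude, third-order median smoothing.
#'
#' @param s an [accel_ts()].
#' @return A smoothed [magnitude_series()].
#' @export
preprocess_sensor <- function(s) {
  median_smooth(magnitude(interpolate_missing(s)))
}
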