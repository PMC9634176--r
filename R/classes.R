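#' @title Core data containers
#' @description S3 containers shared by all pipeline stages: tri-axial
#'   accelerometry, one-dimensional magnitude series, and behavioural
#'   annotation tracks.
#' @name rattlewave-classes
#' @keywords internal
NULL

CONDITIONS <- c("MOTHER_NOT_PROVIDING", "MOTHER_PROVIDING")
TIERS <- c("CLAP", "RATTLING")

#' Tri-axial acceleration time series
#'
#' One wrist sensor's uniformly sampled tri-axial acceleration with a
#' per-sample missing mask. Time is on the sensor clock; units are whatever
#' the sensor reports (the pipeline is unit-agnostic: every threshold is
#' relative to within-window statistics).
#'
#' @param t numeric, sample times in seconds on a uniform grid.
#' @param ax,ay,az numeric, acceleration along the three sensor axes.
#' @param fs sampling rate in Hz.
#' @param missing logical mask, `TRUE` where the sample is absent (axis
#'   values undefined until [interpolate_missing()]).
#' @return An object of class `accel_ts`.
#' @export
accel_ts <- function(t, ax, ay, az, fs, missing = NULL) {
  n <- length(t)
  if (is.null(missing)) missing <- rep(FALSE, n)
  stopifnot(length(ax) == n, length(ay) == n, length(az) == n,
            length(missing) == n)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (n >= 2) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-9 * max(1, 1 / fs)))
      stop("time grid is not uniform at spacing 1/fs (tolerance 1e-9)")
  }
  structure(
    list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), fs = fs, missing = as.logical(missing)),
    class = "accel_ts")
}

#' @export
print.accel_ts <- function(x, ...) {
  cat(sprintf("<accel_ts> %d samples @ %g Hz (%.2f s), %d missing\n",
              length(x$t), x$fs, length(x$t) / x$fs, sum(x$missing)))
  invisible(x)
}

#' @export
length.accel_ts <- function(x) length(x$t)

#' One-dimensional acceleration magnitude series
#'
#' The normalized acceleration `sqrt(ax^2 + ay^2 + az^2)`, optionally
#' median-smoothed. Produced by [magnitude()] and [median_smooth()].
#'
#' @param t sample times in seconds.
#' @param acc non-negative magnitude values.
#' @param fs sampling rate in Hz.
#' @param provenance `"RAW_NORM"` straight from the Euclidean norm, or
#'   `"SMOOTHED"` after the third-order median filter.
#' @return An object of class `magnitude_series`.
#' @export
magnitude_series <- function(t, acc, fs, provenance = c("RAW_NORM", "SMOOTHED")) {
  provenance <- match.arg(provenance)
  stopifnot(length(t) == length(acc))
  if (any(acc < 0)) stop("magnitude values must be non-negative")
  structure(list(t = as.numeric(t), acc = as.numeric(acc), fs = fs,
                 provenance = provenance),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %d samples @ %g Hz, %s\n",
              length(x$t), x$fs, x$provenance))
  invisible(x)
}

#' @export
length.magnitude_series <- function(x) length(x$t)

#' Behavioural annotation track
#'
#' Ordered labelled intervals exported by a video coder: `CLAP` intervals
#' used for sensor/video synchronisation and `RATTLING` episodes carrying a
#' condition label ("mother providing rhythm" vs "not providing").
#' Intervals are half-open `[onset, offset)` when rasterised to samples.
#'
#' @param tier character, one of `"CLAP"`, `"RATTLING"` per interval.
#' @param onset_s,offset_s interval bounds in seconds (`offset_s > onset_s`).
#' @param label optional condition label (`"MOTHER_NOT_PROVIDING"` /
#'   `"MOTHER_PROVIDING"`), `NA` for clap intervals.
#' @return An `annotation_track`: a data frame with columns
#'   `tier`, `onset_s`, `offset_s`, `label`, sorted by onset.
#' @export
annotation_track <- function(tier = character(), onset_s = numeric(),
                             offset_s = numeric(), label = NA_character_) {
  n <- length(tier)
  label <- if (n == 0) character(0) else rep_len(as.character(label), n)
  stopifnot(length(onset_s) == n, length(offset_s) == n)
  if (!all(tier %in% TIERS))
    stop("unknown tier(s): ", paste(setdiff(tier, TIERS), collapse = ", "))
  bad_lab <- !is.na(label) & !(label %in% CONDITIONS)
  if (any(bad_lab))
    stop("unknown label(s): ", paste(unique(label[bad_lab]), collapse = ", "))
  if (any(offset_s <= onset_s))
    stop("all intervals must satisfy offset_s > onset_s")
  df <- data.frame(tier = tier, onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s), label = label,
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
  rownames(df) <- NULL
  # within-tier overlap check (half-open intervals: touching is fine)
  for (tr in unique(df$tier)) {
    sub <- df[df$tier == tr, , drop = FALSE]
    if (nrow(sub) >= 2) {
      ov <- which(sub$onset_s[-1] < sub$offset_s[-nrow(sub)])
      if (length(ov))
        stop(sprintf(
          "overlapping %s intervals: [%g, %g) and [%g, %g)", tr,
          sub$onset_s[ov[1]], sub$offset_s[ov[1]],
          sub$onset_s[ov[1] + 1], sub$offset_s[ov[1] + 1]))
    }
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d intervals (%d CLAP, %d RATTLING)\n",
              nrow(x), sum(x$tier == "CLAP"), sum(x$tier == "RATTLING")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Subset the intervals of a track, keeping the class
#' @keywords internal
#' @noRd
track_subset <- function(track, keep) {
  df <- as.data.frame(track)[keep, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}
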