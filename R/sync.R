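#' Detect supra-threshold movement events in a magnitude series
#'
#' Binarizes the series inside an analysis window: a sample is active ("1")
#' when it exceeds the window mean plus one standard deviation (population
#' SD, a fixed convention for bit-reproducibility); everything outside the
#' window is 0. Maximal runs of active samples separated by 50 ms or less
#' are merged into a single event, so extremely short or nearly touching
#' bursts are not double-counted.
#'
#' @param m a [magnitude_series()].
#' @param window `(start_s, end_s)` analysis period (half-open on samples).
#' @param merge_gap_s runs separated by at most this gap are merged.
#' @return An `event_series`: list with the binary vector `b`, the event
#'   table `events` (`onset_s`, `offset_s`), `window`, `threshold`,
#'   `merge_gap_s`, `t` and `fs`.
#' @export
detect_events <- function(m, window, merge_gap_s = 0.050) {
  stopifnot(inherits(m, "magnitude_series"), length(window) == 2)
  fs <- m$fs
  idx <- which(m$t >= window[1] & m$t < window[2])
  if (length(idx) < 2) stop("analysis window contains fewer than 2 samples")
  vals <- m$acc[idx]
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))
  if (sdev == 0)
    stop("zero-variance window: the mean + 1 SD threshold is undefined")
  threshold <- mu + sdev
  b <- numeric(length(m$t))
  b[idx] <- as.numeric(vals > threshold)
  runs <- binary_runs(b)
  events <- merge_runs(runs, fs, merge_gap_s)
  ev_df <- if (nrow(events)) {
    data.frame(onset_s = m$t[events$start],
               offset_s = m$t[events$end] + 1 / fs)
  } else {
    data.frame(onset_s = numeric(0), offset_s = numeric(0))
  }
  structure(list(b = b, events = ev_df, window = window,
                 threshold = threshold, merge_gap_s = merge_gap_s,
                 t = m$t, fs = fs),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events in window [%g, %g) s (threshold %.4g)\n",
              nrow(x$events), x$window[1], x$window[2], x$threshold))
  invisible(x)
}

# maximal runs of 1s: data.frame(start, end) in sample indices
binary_runs <- function(b) {
  r <- rle(b > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# merge runs whose inter-run gap is <= merge_gap_s (gap in whole samples)
merge_runs <- function(runs, fs, merge_gap_s) {
  if (nrow(runs) <= 1) return(runs)
  max_gap <- floor(merge_gap_s * fs + 1e-9)
  out_start <- runs$start[1]
  out_end <- runs$end[1]
  res <- list()
  for (i in 2:nrow(runs)) {
    gap <- runs$start[i] - out_end - 1L
    if (gap <= max_gap) {
      out_end <- runs$end[i]
    } else {
      res[[length(res) + 1L]] <- c(out_start, out_end)
      out_start <- runs$start[i]
      out_end <- runs$end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_start, out_end)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Rasterize annotation intervals of one tier to a binary series
#'
#' Sample `i` (time `(i-1)/fs`) is 1 when it falls inside any interval of
#' the tier, using the half-open `[onset, offset)` convention so adjacent
#' intervals never double-count a sample.
#'
#' @param track an [annotation_track()].
#' @param tier `"CLAP"` or `"RATTLING"`.
#' @param fs sampling rate of the output series in Hz.
#' @param extent_s length of the output series in seconds.
#' @return Numeric 0/1 vector of length `round(extent_s * fs)`.
#' @export
binarize_annotations <- function(track, tier, fs, extent_s) {
  stopifnot(inherits(track, "annotation_track"))
  tier <- match.arg(tier, TIERS)
  n <- round(extent_s * fs)
  b <- numeric(n)
  sub <- track[track$tier == tier, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- ceiling(sub$onset_s[i] * fs - 1e-9) + 1L
    hi <- ceiling(sub$offset_s[i] * fs - 1e-9)  # last sample with t < offset
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (hi >= lo) b[lo:hi] <- 1
  }
  b
}

#' Estimate the sensor-video lag by diagonal cross-recurrence profile
#'
#' Computes the recurrence rate between two binary event series as a
#' function of relative lag: for each integer-sample lag in
#' `[-window_s, +window_s]` the number of co-occurring ones, normalized by
#' the largest attainable number of matches (the smaller of the two
#' series' total one-counts), so a perfect alignment scores 1. The
#' estimated lag is the profile's argmax, in the video-minus-sensor sense:
#' subtracting `lag_s` from annotation times moves them onto the sensor
#' clock (see [align_track()]).
#'
#' Mirrors the two-window procedure used for clap synchronisation: a
#' correct full alignment matches essentially every clap (rate near 1), so
#' if the 6 s search matches less than `widen_floor` of the claps — e.g.
#' when the true lag lies beyond 6 s and only a chance partial alignment
#' scores — the search is automatically widened to 15 s. Estimates whose
#' final peak rate falls below `peak_floor` carry a low-confidence flag.
#'
#' @param sensor_claps binary 0/1 series from [detect_events()]'s `b` (the
#'   clap-window binarized sensor magnitude).
#' @param video_claps binary 0/1 series from [binarize_annotations()], same
#'   sampling rate.
#' @param fs sampling rate of both series in Hz.
#' @param window_s half-width of the lag search in seconds (6 or 15).
#' @param peak_floor recurrence-rate floor below which the estimate is
#'   flagged low-confidence.
#' @param widen_floor peak rate below which the 6 s search is rerun at
#'   15 s (when `auto_widen`).
#' @param auto_widen widen a weak 6 s search to 15 s.
#' @return A `lag_estimate`: list with `lag_s`, `window_s`, `lags_s`,
#'   `profile`, `peak_rate` and `low_confidence`.
#' @export
estimate_lag <- function(sensor_claps, video_claps, fs, window_s = 6,
                         peak_floor = 0.1, widen_floor = 0.5,
                         auto_widen = TRUE) {
  x <- as.numeric(sensor_claps > 0)
  y <- as.numeric(video_claps > 0)
  if (sum(x) == 0 || sum(y) == 0)
    stop("both series must contain at least one active sample")
  est <- dcrp_profile(x, y, fs, window_s)
  if (auto_widen && window_s < 15 && est$peak_rate < widen_floor) {
    est <- dcrp_profile(x, y, fs, 15)
  }
  est$low_confidence <- est$peak_rate < peak_floor
  if (est$low_confidence)
    warning(sprintf("low-confidence lag estimate: peak recurrence rate %.3f < %.3f",
                    est$peak_rate, peak_floor))
  class(est) <- "lag_estimate"
  est
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> lag %.4f s (window %g s, peak rate %.3f%s)\n",
              x$lag_s, x$window_s, x$peak_rate,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

# recurrence profile over lags -L..L samples; lag ell means the video series
# matches the sensor series delayed by ell (video = sensor + ell samples)
dcrp_profile <- function(x, y, fs, window_s) {
  nx <- length(x)
  ny <- length(y)
  L <- round(window_s * fs)
  # cross-correlation via FFT: cc[ell] = sum_i x[i] * y[i + ell]
  nfft <- stats::nextn(nx + ny, 2)
  fx <- stats::fft(c(x, numeric(nfft - nx)))
  fy <- stats::fft(c(y, numeric(nfft - ny)))
  cc_full <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / nfft
  # cc_full[k+1] corresponds to ell = k (mod nfft); negative lags wrap
  lags <- (-L):L
  cc <- cc_full[(lags %% nfft) + 1L]
  cc <- pmax(round(cc), 0)
  # attainable matches: the smaller total count of ones. A lag-constant
  # denominator keeps profiles comparable across lags; normalizing inside
  # each overlap would reward lags whose overlap strands a single event
  denom <- min(sum(x), sum(y))
  profile <- cc / denom
  # argmax; ties: smallest |lag|, then negative before positive
  best <- order(-profile, abs(lags), lags)[1]
  list(lag_s = lags[best] / fs, window_s = window_s,
       lags_s = lags / fs, profile = profile,
       peak_rate = profile[best])
}

#' Shift an annotation track onto the sensor clock
#'
#' Subtracts the estimated video-minus-sensor lag from every onset and
#' offset. When the sensor extent is supplied, intervals are clipped to it;
#' intervals falling entirely outside are dropped with a warning.
#'
#' @param track an [annotation_track()] on the video clock.
#' @param lag a `lag_estimate` from [estimate_lag()], or a single number
#'   (video-minus-sensor seconds).
#' @param extent_s optional sensor extent `(0, extent_s)` for clipping.
#' @return The aligned [annotation_track()].
#' @export
align_track <- function(track, lag, extent_s = NULL) {
  stopifnot(inherits(track, "annotation_track"))
  lag_s <- if (inherits(lag, "lag_estimate")) lag$lag_s else as.numeric(lag)
  on <- track$onset_s - lag_s
  off <- track$offset_s - lag_s
  if (!is.null(extent_s)) {
    dropped <- off <= 0 | on >= extent_s
    if (any(dropped))
      warning(sprintf("%d interval(s) fall outside the sensor extent and were dropped",
                      sum(dropped)))
    on <- pmax(on[!dropped], 0)
    off <- pmin(off[!dropped], extent_s)
    return(annotation_track(track$tier[!dropped], on, off,
                            track$label[!dropped]))
  }
  annotation_track(track$tier, on, off, track$label)
}

#' Clap-based synchronisation of one session
#'
#' Convenience chain: detect claps in the sensor magnitude inside the clap
#' window, rasterize the video clap tier, estimate the lag (with automatic
#' 6 s to 15 s widening) and return the aligned track together with the
#' estimate.
#'
#' @param m smoothed [magnitude_series()] of one arm.
#' @param video_track [annotation_track()] on the video clock.
#' @param clap_window `(start_s, end_s)` sensor-clock period containing the
#'   claps (the study selected it by eye; here it is explicit input).
#' @param window_s initial lag search half-width in seconds.
#' @return List with `aligned` (track on the sensor clock), `lag`
#'   (`lag_estimate`) and `claps` (`event_series`).
#' @export
sync_session <- function(m, video_track, clap_window, window_s = 6) {
  claps <- detect_events(m, clap_window)
  extent_s <- length(m$t) / m$fs
  # rasterize the video claps over a grid long enough to cover the lag range
  video_extent <- max(extent_s, max(video_track$offset_s) + 1)
  vb <- binarize_annotations(video_track, "CLAP", m$fs, video_extent)
  lag <- estimate_lag(claps$b, vb, m$fs, window_s = window_s)
  aligned <- align_track(video_track, lag, extent_s = extent_s)
  list(aligned = aligned, lag = lag, claps = claps)
}

#' Alignment quality-control plot
#'
#' Static replacement for the study's visual-inspection GUI: overlays the
#' sensor clap raster and the video clap raster shifted by the estimated
#' lag, plus the recurrence profile.
#'
#' @param claps `event_series` from [detect_events()] on the clap window.
#' @param video_claps binary series from [binarize_annotations()].
#' @param lag `lag_estimate`.
#' @param fs sampling rate in Hz.
#' @return Invisibly `NULL`; draws on the active device.
#' @export
plot_alignment <- function(claps, video_claps, lag, fs) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t_s <- claps$t
  shift <- round(lag$lag_s * fs)
  vshift <- numeric(length(t_s))
  src <- seq_along(t_s) + shift
  ok <- src >= 1 & src <= length(video_claps)
  vshift[ok] <- video_claps[src[ok]]
  graphics::plot(t_s, claps$b, type = "h", col = "grey30",
                 xlab = "sensor time [s]", ylab = "claps",
                 main = sprintf("alignment at lag %.3f s", lag$lag_s))
  graphics::lines(t_s, vshift * 0.8, type = "h", col = "firebrick")
  graphics::plot(lag$lags_s, lag$profile, type = "l",
                 xlab = "lag [s]", ylab = "recurrence rate",
                 main = "diagonal cross-recurrence profile")
  graphics::abline(v = lag$lag_s, col = "firebrick", lty = 2)
  invisible(NULL)
}
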