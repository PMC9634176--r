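#' @title Morlet wavelet coherence of bimanual movement
#' @description FFT-based analytic Morlet continuous wavelet transform and
#'   smoothed wavelet coherence between the two arms' magnitude series,
#'   band-averaged over the infant rattling band (0.5-2.5 Hz), with a
#'   shuffled-surrogate null for the band mean.
#' @name rattlewave-coherence
#' @keywords internal
NULL

# time-frequency geometry shared by every transform on series of length n:
# dyadic scale grid, Fourier-domain wavelet filters, Gaussian time-smoothing
# multipliers, scale-smoothing boxcar width, cone of influence
wc_geometry <- function(n, fs, omega0 = 6, dj = 1 / 12,
                        f_min = 0.25, f_max = 5, scales = NULL,
                        pad_mult = 4) {
  stopifnot(n >= 2, fs > 0, f_min > 0, f_max > f_min)
  dt <- 1 / fs
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))  # Fourier factor: period = ff * scale
  if (is.null(scales)) {
    s_min <- 1 / (ff * f_max)
    s_max <- 1 / (ff * f_min)
    J <- ceiling(log2(s_max / s_min) / dj)
    scales <- s_min * 2^(dj * (0:J))
  }
  freqs <- 1 / (ff * scales)
  ns <- length(scales)
  # pad: power of two with enough slack for the widest wavelet/smoother
  nfft <- stats::nextn(n, 2)
  if (nfft - n < pad_mult * max(scales) * fs) nfft <- 2 * nfft
  k <- 0:(nfft - 1)
  omega <- ifelse(k <= nfft / 2, k, k - nfft) * (2 * pi / (nfft * dt))
  pos <- omega > 0
  filters <- matrix(0, nfft, ns)
  for (j in seq_len(ns)) {
    filters[pos, j] <- pi^(-0.25) * sqrt(2 * pi * scales[j] / dt) *
      exp(-0.5 * (scales[j] * omega[pos] - omega0)^2)
  }
  gmult <- matrix(0, nfft, ns)
  for (j in seq_len(ns))
    gmult[, j] <- exp(-0.5 * (scales[j] * omega)^2)
  boxw <- max(1L, round(0.6 / dj))
  if (boxw %% 2L == 0L) boxw <- boxw + 1L
  # cone of influence: minimum reliable frequency per time sample
  # (e-folding time sqrt(2)*scale of the Morlet envelope)
  d <- pmax((pmin(seq_len(n) - 1L, n - seq_len(n)) + 0.5) / fs, 0.5 / fs)
  coi_freq <- sqrt(2) / (ff * d)
  list(n = n, fs = fs, dt = dt, omega0 = omega0, dj = dj, ff = ff,
       scales = scales, freqs = freqs, ns = ns, nfft = nfft,
       filters = filters, gmult = gmult, boxw = boxw, coi_freq = coi_freq,
       inv_scale = matrix(rep(1 / scales, each = n), n, ns))
}

# CWT of a numeric vector under a prepared geometry: n x ns complex matrix
wc_cwt <- function(x, geom) {
  xd <- x - mean(x)
  fx <- stats::fft(c(xd, numeric(geom$nfft - geom$n)))
  W <- stats::mvfft(fx * geom$filters, inverse = TRUE) / geom$nfft
  W[seq_len(geom$n), , drop = FALSE]
}

# smoothing operator S: Gaussian in time with SD equal to the scale
# (applied per scale column in the Fourier domain, zero-padded), then a
# fixed-width boxcar across scales (~0.6 octave, truncated and
# renormalized at the grid edges). All weights are non-negative, so the
# Cauchy-Schwarz inequality bounds the resulting coherence in [0, 1].
wc_smooth <- function(M, geom) {
  P <- rbind(M, matrix(0, geom$nfft - geom$n, geom$ns))
  F0 <- stats::mvfft(P)
  sm <- stats::mvfft(F0 * geom$gmult, inverse = TRUE)[seq_len(geom$n), ,
                                                      drop = FALSE] / geom$nfft
  h <- geom$boxw %/% 2L
  if (h == 0L) return(sm)
  out <- sm
  for (j in seq_len(geom$ns)) {
    lo <- max(1L, j - h)
    hi <- min(geom$ns, j + h)
    out[, j] <- rowMeans(sm[, lo:hi, drop = FALSE])
  }
  out
}

# raw (pre-clipping) coherence matrix, n x ns
wc_raw_matrix <- function(x, y, geom, smoothing = TRUE) {
  X <- wc_cwt(x, geom)
  Y <- wc_cwt(y, geom)
  Wxy <- X * Conj(Y) * geom$inv_scale
  Pxx <- (Re(X)^2 + Im(X)^2) * geom$inv_scale
  Pyy <- (Re(Y)^2 + Im(Y)^2) * geom$inv_scale
  if (smoothing) {
    Sxy <- wc_smooth(Wxy, geom)
    Sxx <- Re(wc_smooth(Pxx, geom))
    Syy <- Re(wc_smooth(Pyy, geom))
  } else {
    Sxy <- Wxy; Sxx <- Pxx; Syy <- Pyy
  }
  raw <- (Re(Sxy)^2 + Im(Sxy)^2) / (Sxx * Syy)
  if (smoothing) {
    # cells with smoothed auto-power this far below the spectrum peak are
    # dominated by FFT roundoff (narrowband inputs): numerically undefined
    raw[Sxx < 1e-9 * max(Sxx) | Syy < 1e-9 * max(Syy)] <- NA_real_
  }
  raw
}

as_mag_vector <- function(x) {
  if (inherits(x, "magnitude_series")) x$acc else as.numeric(x)
}
mag_fs <- function(x, fs) {
  if (inherits(x, "magnitude_series")) x$fs
  else if (is.null(fs)) stop("supply `fs` for plain numeric input") else fs
}

#' Continuous wavelet transform (analytic Morlet)
#'
#' Transforms a magnitude series with the analytic Morlet wavelet (centre
#' frequency `omega0`, default 6) over a dyadic scale grid of `1/dj` voices
#' per octave spanning `f_min`-`f_max` Hz — a margin around the 0.5-2.5 Hz
#' rattling band. Computed in the Fourier domain with zero padding; the
#' cone of influence marks, per time sample, the lowest frequency not yet
#' contaminated by edge effects (e-folding convention).
#'
#' @param m a [magnitude_series()] or numeric vector.
#' @param fs sampling rate in Hz (taken from `m` when it is a series).
#' @param omega0 Morlet centre frequency (rad).
#' @param dj scale resolution in octaves (1/12 = 12 voices per octave).
#' @param f_min,f_max analysed frequency range in Hz.
#' @return A `cwt_result`: list with `coeffs` (complex, scale x time, rows
#'   ordered by decreasing frequency), `freqs`, `scales`, `coi` (minimum
#'   reliable frequency per time sample), `fs`, `omega0`, `dj`.
#' @export
morlet_cwt <- function(m, fs = NULL, omega0 = 6, dj = 1 / 12,
                       f_min = 0.25, f_max = 5) {
  x <- as_mag_vector(m)
  fs <- mag_fs(m, fs)
  if (length(x) < 2) stop("input too short for a wavelet transform")
  geom <- wc_geometry(length(x), fs, omega0, dj, f_min, f_max)
  short <- length(x) < 2 * fs / f_min
  if (short)
    warning(sprintf("input shorter than two periods of the lowest analysed frequency (%g Hz)",
                    f_min))
  W <- wc_cwt(x, geom)
  structure(list(coeffs = t(W), freqs = geom$freqs, scales = geom$scales,
                 coi = geom$coi_freq, fs = fs, omega0 = omega0, dj = dj,
                 short_input = short),
            class = "cwt_result")
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("<cwt_result> %d scales (%.3g-%.3g Hz) x %d samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$coeffs), x$fs))
  invisible(x)
}

#' Smoothed wavelet coherence between two magnitude series
#'
#' The squared magnitude of the smoothed cross-wavelet spectrum, normalized
#' by the product of the two smoothed auto-spectra: values near 1 mean the
#' two arms share a consistent phase relation at that frequency and time,
#' values near 0 mean none. Spectra are scale-normalized (divided by scale)
#' before smoothing; the smoothing operator is a scale-proportional
#' Gaussian in time followed by a ~0.6-octave boxcar across scales. Without
#' smoothing the ratio degenerates to 1 identically — keep `smoothing`
#' enabled for any real use (the option exists as a negative control).
#'
#' Numerical overshoot beyond `[0, 1]` up to `clip_tol` is clipped; larger
#' violations raise an error, since they indicate a broken smoother.
#' Time-frequency cells whose smoothed auto-power lies more than nine
#' orders of magnitude below the spectrum peak (possible only for nearly
#' noiseless narrowband inputs) are numerically indeterminate and returned
#' as `NA`; [band_average()] skips them.
#'
#' @param x,y [magnitude_series()] (or numeric vectors) of equal length and
#'   sampling rate; neither may be constant.
#' @param fs sampling rate for plain numeric input.
#' @param omega0,dj,f_min,f_max transform parameters as in [morlet_cwt()].
#' @param smoothing logical; disable only as a degeneracy check.
#' @param clip_tol tolerated numerical overshoot.
#' @param band `(f_lo, f_hi)` band in Hz for the scalar `band_mean`.
#' @return A `coherence_result`: `wc` (scale x time, clipped to `[0, 1]`),
#'   `freqs`, `scales`, `coi`, `band_mean`, `raw_range` (pre-clipping
#'   extremes), `smoothing_params`, `fs`.
#' @export
wavelet_coherence <- function(x, y, fs = NULL, omega0 = 6, dj = 1 / 12,
                              f_min = 0.25, f_max = 5, smoothing = TRUE,
                              clip_tol = 1e-6, band = c(0.5, 2.5)) {
  xv <- as_mag_vector(x)
  yv <- as_mag_vector(y)
  if (length(xv) != length(yv)) stop("series lengths differ")
  fsx <- mag_fs(x, fs)
  fsy <- mag_fs(y, fs)
  if (abs(fsx - fsy) > 1e-9) stop("sampling rates differ")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("constant input: wavelet coherence is undefined (zero power)")
  geom <- wc_geometry(length(xv), fsx, omega0, dj, f_min, f_max)
  raw <- wc_raw_matrix(xv, yv, geom, smoothing = smoothing)
  rng <- range(raw, na.rm = TRUE)
  if (rng[2] > 1 + clip_tol || rng[1] < -clip_tol)
    stop(sprintf("coherence outside [0, 1] beyond tolerance (range %.3g..%.3g): smoothing is broken",
                 rng[1], rng[2]))
  wc <- pmin(pmax(raw, 0), 1)
  res <- structure(
    list(wc = t(wc), freqs = geom$freqs, scales = geom$scales,
         coi = geom$coi_freq, raw_range = rng,
         smoothing_params = list(time = "gaussian, SD = scale",
                                 scale = sprintf("boxcar, %d scales (~0.6 octave)",
                                                 geom$boxw),
                                 enabled = smoothing,
                                 omega0 = omega0, dj = dj),
         fs = fsx),
    class = "coherence_result")
  res$band_mean <- band_average(res, band[1], band[2])
  res
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d scales x %d samples, band mean %.3f\n",
              nrow(x$wc), ncol(x$wc), x$band_mean))
  invisible(x)
}

#' @export
plot.coherence_result <- function(x, ...) {
  t_s <- (seq_len(ncol(x$wc)) - 1) / x$fs
  graphics::image(t_s, log2(rev(x$freqs)), t(x$wc[rev(seq_len(nrow(x$wc))), ]),
                  xlab = "time [s]", ylab = "log2 frequency [Hz]",
                  main = "wavelet coherence", zlim = c(0, 1), ...)
  graphics::lines(t_s, log2(pmin(x$coi, max(x$freqs))), lty = 2)
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted mean of the coherence matrix over the scale rows whose centre
#' frequency lies in `[f_lo, f_hi]` and all time columns. By default all
#' times are included, matching the band-mean the study reports over the
#' full episode series; `coi_exclude = TRUE` drops cells inside the cone of
#' influence instead.
#'
#' @param c a `coherence_result`.
#' @param f_lo,f_hi band edges in Hz.
#' @param coi_exclude drop time-frequency cells with unreliable edges.
#' @return Scalar in `[0, 1]`.
#' @export
band_average <- function(c, f_lo = 0.5, f_hi = 2.5, coi_exclude = FALSE) {
  rows <- which(c$freqs >= f_lo & c$freqs <= f_hi)
  if (!length(rows)) stop("no scale rows inside the requested band")
  sub <- c$wc[rows, , drop = FALSE]
  if (all(is.na(sub))) stop("entire band is numerically undefined")
  if (!coi_exclude) return(mean(sub, na.rm = TRUE))
  mask <- outer(c$freqs[rows], c$coi, `>=`)
  if (!any(mask)) stop("entire band lies inside the cone of influence")
  mean(sub[mask], na.rm = TRUE)
}

#' Shuffled-surrogate null for the band-averaged coherence
#'
#' Each iteration independently permutes the samples of both series
#' (destroying all temporal structure while preserving the amplitude
#' distributions), recomputes the band-averaged wavelet coherence, and
#' records it; the observed value comes from the unshuffled inputs. For
#' speed, only the scale rows needed for the band (plus the
#' scale-smoothing margin) are computed, with lighter zero padding, in a
#' compiled kernel; the observed value and every null draw go through the
#' identical restricted computation, so the comparison is exact even
#' though the band mean can differ from the full-matrix value by tiny
#' edge-padding effects.
#'
#' @param x,y inputs as in [wavelet_coherence()].
#' @param n_iter number of shuffles (the study used 1000).
#' @param seed integer seed for the permutation stream.
#' @param fs sampling rate for plain numeric input.
#' @param f_lo,f_hi band in Hz.
#' @param omega0,dj,f_min,f_max transform parameters.
#' @return A `surrogate_null`: `observed`, `null_values` (length
#'   `n_iter`), `n_iter`, `seed`, and the empirical exceedance
#'   `p_value = (1 + #{null >= observed}) / (n_iter + 1)`.
#' @export
surrogate_null <- function(x, y, n_iter = 1000, seed = 1, fs = NULL,
                           f_lo = 0.5, f_hi = 2.5, omega0 = 6, dj = 1 / 12,
                           f_min = 0.25, f_max = 5) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  xv <- as_mag_vector(x)
  yv <- as_mag_vector(y)
  if (length(xv) != length(yv)) stop("series lengths differ")
  fs <- mag_fs(x, fs)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("constant input: wavelet coherence is undefined (zero power)")
  n <- length(xv)
  # same dyadic scale values as the full grid, restricted to the band rows
  # plus the boxcar half-width (so no band row's scale smoothing is
  # truncated by the restriction), on a lighter padding
  full_ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  full <- wc_geometry(n, fs, omega0, dj, f_min, f_max)
  h <- full$boxw %/% 2L
  rows <- which(full$freqs >= f_lo & full$freqs <= f_hi)
  if (!length(rows)) stop("no scale rows inside the requested band")
  keep <- max(1L, min(rows) - h):min(full$ns, max(rows) + h)
  sub <- wc_geometry(n, fs, omega0, dj, f_min, f_max,
                     scales = full$scales[keep], pad_mult = 2)
  band_rows <- which(sub$freqs >= f_lo & sub$freqs <= f_hi)
  observed <- .wc_band_mean_cpp(xv, yv, sub$filters, sub$gmult,
                                1 / sub$scales, band_rows - 1L, sub$boxw)
  perms <- with_seed(seed, {
    px <- matrix(0L, n, n_iter)
    py <- matrix(0L, n, n_iter)
    for (i in seq_len(n_iter)) {
      px[, i] <- sample.int(n)
      py[, i] <- sample.int(n)
    }
    list(px = px, py = py)
  })
  null_values <- drop(.wc_band_mean_perm_cpp(xv, yv, sub$filters, sub$gmult,
                                             1 / sub$scales, band_rows - 1L,
                                             sub$boxw, perms$px, perms$py))
  structure(list(observed = observed, null_values = null_values,
                 n_iter = n_iter, seed = seed,
                 p_value = (1 + sum(null_values >= observed)) / (n_iter + 1)),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> observed %.3f vs null %.3f [%.3f, %.3f] (%d shuffles, p = %.4f)\n",
              x$observed, mean(x$null_values),
              stats::quantile(x$null_values, 0.025),
              stats::quantile(x$null_values, 0.975), x$n_iter, x$p_value))
  invisible(x)
}

#' Group-level test of observed coherence against the shuffled null
#'
#' Paired two-sided t-test of the per-visit observed band means against the
#' per-visit means of their surrogate nulls — the group-level control
#' showing that between-arm coherence does not arise from chance.
#'
#' @param observed numeric vector of per-visit observed band means.
#' @param null_means numeric vector of per-visit surrogate-null means,
#'   same order.
#' @return List with `t_stat`, `df`, `p_value`, `mean_diff`, and
#'   `degenerate` (`TRUE` when the paired differences have zero variance).
#' @export
group_null_test <- function(observed, null_means) {
  if (length(observed) != length(null_means))
    stop("observed and null_means must have equal length")
  if (length(observed) < 2) stop("need at least 2 paired visits")
  d <- observed - null_means
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (abs(mean(d)) < 1e-12)
      return(list(t_stat = 0, df = length(d) - 1, p_value = 1,
                  mean_diff = 0, degenerate = TRUE))
    warning("zero-variance paired differences: t-test is degenerate")
    return(list(t_stat = NA_real_, df = length(d) - 1, p_value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(observed, null_means, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Time-averaged wavelet power spectrum of a single hand
#'
#' The time-mean of the squared CWT magnitude per scale row — the per-visit
#' single-hand spectrum used to describe developmental changes in movement
#' frequency content.
#'
#' @param m a [magnitude_series()] or numeric vector.
#' @param fs sampling rate for plain numeric input.
#' @param ... transform parameters passed to [morlet_cwt()].
#' @return Data frame with `freq_hz` and `power`, ordered by decreasing
#'   frequency.
#' @export
single_hand_spectrum <- function(m, fs = NULL, ...) {
  cw <- morlet_cwt(m, fs = fs, ...)
  data.frame(freq_hz = cw$freqs,
             power = rowMeans(Mod(cw$coeffs)^2))
}
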