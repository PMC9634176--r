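#' Specify one synthetic rattling episode
#'
#' An episode is a time window in which the simulated infant shakes the
#' rattle: `n_movements` oscillatory packets are placed in the window on
#' each arm. A packet is a Tukey-windowed (raised-cosine-tapered) quadrature
#' oscillation at `burst_freq_hz` on the two gravity-orthogonal axes —
#' a rotational wrist shake — whose acceleration magnitude is one smooth
#' bump, so one packet corresponds to exactly one discrete rattling
#' movement and ground-truth movement counts are well defined. `coupling`
#' controls how tightly the right arm follows the left: at 1 the right arm
#' repeats the left arm's packet times and carrier phases (phase-locked);
#' at 0 its packet layout is drawn independently and its carrier phases
#' are scrambled, removing any consistent bimanual relation.
#'
#' @param onset_s,offset_s episode bounds in seconds, `offset_s > onset_s`.
#' @param burst_freq_hz carrier frequency of the shaking bursts in Hz
#'   (typically 0.5–2.5, the infant rattling band).
#' @param n_movements number of packets per arm, at least 1.
#' @param coupling left–right phase coupling in `[0, 1]`.
#' @param amplitude packet peak amplitude in acceleration units (same units
#'   as the noise SD and gravity offset).
#' @param condition `"MOTHER_NOT_PROVIDING"` or `"MOTHER_PROVIDING"`.
#' @return An object of class `episode_spec`.
#' @export
episode_spec <- function(onset_s, offset_s, burst_freq_hz = 2,
                         n_movements = 3, coupling = 1, amplitude = 0.8,
                         condition = "MOTHER_NOT_PROVIDING") {
  if (offset_s <= onset_s) stop("episode must have offset_s > onset_s")
  if (n_movements < 1) stop("n_movements must be at least 1")
  if (burst_freq_hz < 0.1 || burst_freq_hz > 5)
    stop("burst_freq_hz must lie in [0.1, 5] Hz")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (amplitude <= 0) stop("amplitude must be positive")
  condition <- match.arg(condition, CONDITIONS)
  structure(list(onset_s = onset_s, offset_s = offset_s,
                 burst_freq_hz = burst_freq_hz,
                 n_movements = as.integer(n_movements),
                 coupling = coupling, amplitude = amplitude,
                 condition = condition),
            class = "episode_spec")
}

#' Configure a synthetic dyad session
#'
#' Defaults emulate the recording setup of the study this package models:
#' roughly five-minute play sessions sampled at 60 Hz, a handful of maternal
#' claps near the session start for sensor/video synchronisation, and a
#' sensor-to-video clock offset of up to +/-15 s. The noise model is
#' additive white Gaussian on each axis plus a constant gravity offset on
#' one axis — the simplest model giving a realistic nonzero magnitude
#' baseline. Amplitudes are in arbitrary acceleration units (nominally g);
#' the pipeline only ever uses within-window relative thresholds.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate in Hz.
#' @param n_claps number of clap transients.
#' @param clap_window `(start_s, end_s)` period containing the claps.
#' @param true_lag_s video-minus-sensor clock offset in seconds, in
#'   `[-15, 15]`; annotation times are sensor times plus this lag.
#' @param episodes list of [episode_spec()] objects, pairwise non-overlapping.
#' @param noise_sd per-axis white noise SD.
#' @param gravity_offset constant offset on the z axis.
#' @param clap_amplitude clap spike peak (at least `5 * noise_sd`).
#' @param dropout_rate fraction of samples marked missing (exercises the
#'   spline interpolation stage); 0 disables dropout.
#' @param rng_seed integer seed governing all randomness of the session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration_s = 300, fs = 60, n_claps = 4,
                           clap_window = c(2, 20), true_lag_s = 0,
                           episodes = list(), noise_sd = 0.05,
                           gravity_offset = 1, clap_amplitude = 2,
                           dropout_rate = 0, rng_seed = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (length(clap_window) != 2 || clap_window[1] >= clap_window[2] ||
      clap_window[1] < 0 || clap_window[2] > duration_s)
    stop("clap_window must be an increasing pair within [0, duration_s]")
  if (abs(true_lag_s) > 15) stop("true_lag_s must lie in [-15, 15] s")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (clap_amplitude < 5 * noise_sd)
    stop("clap_amplitude must be at least 5 * noise_sd")
  if (dropout_rate < 0 || dropout_rate > 0.5)
    stop("dropout_rate must lie in [0, 0.5]")
  episodes <- lapply(episodes, function(e) {
    if (!inherits(e, "episode_spec")) stop("episodes must be episode_spec objects")
    if (e$offset_s > duration_s) stop("episode extends past the session end")
    e
  })
  if (length(episodes) >= 2) {
    ord <- order(vapply(episodes, `[[`, 0, "onset_s"))
    episodes <- episodes[ord]
    for (i in seq_len(length(episodes) - 1)) {
      if (episodes[[i + 1]]$onset_s < episodes[[i]]$offset_s)
        stop(sprintf("episodes overlap: [%g, %g) and [%g, %g)",
                     episodes[[i]]$onset_s, episodes[[i]]$offset_s,
                     episodes[[i + 1]]$onset_s, episodes[[i + 1]]$offset_s))
    }
  }
  structure(list(duration_s = duration_s, fs = fs, n_claps = n_claps,
                 clap_window = clap_window, true_lag_s = true_lag_s,
                 episodes = episodes, noise_sd = noise_sd,
                 gravity_offset = gravity_offset,
                 clap_amplitude = clap_amplitude,
                 dropout_rate = dropout_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "session_config")
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-episode substream seed, kept inside 32-bit range
episode_seed <- function(rng_seed, i) {
  (abs(rng_seed) * 10007L + 7919L * i) %% 2147483647L
}

# raised-cosine tapered (Tukey) envelope of one movement packet: flat over
# the central half, cosine rise/fall over each outer quarter. The sharp
# onset mirrors real shakes and keeps threshold chatter at the packet
# edges inside the 50 ms merge window; a full raised cosine rises so
# slowly that sensor noise splits the crossing into separate events
packet_envelope <- function(t, center, half_dur) {
  u <- abs(t - center)
  flat <- half_dur / 2
  env <- numeric(length(t))
  env[u <= flat] <- 1
  taper <- u > flat & u <= half_dur
  env[taper] <- 0.5 * (1 + cos(pi * (u[taper] - flat) / (half_dur - flat)))
  env
}

# place n packet centres inside [lo, hi] with at least min_sep between
# centres: the nominal free time is split by uniform stick-breaking
random_packet_layout <- function(n, lo, hi, min_sep) {
  if (n == 1) return(lo + stats::runif(1) * (hi - lo))
  free <- (hi - lo) - (n - 1) * min_sep
  if (free <= 0) return(seq(lo, hi, length.out = n))
  u <- stats::runif(n + 1)
  g <- free * u / sum(u)
  lo + cumsum(c(g[1], rep(min_sep, n - 1) + g[2:n]))
}

#' Generate a synthetic dyad session with known ground truth
#'
#' Builds both arm sensors' tri-axial streams, the video-coder annotation
#' track (episode and clap intervals on the video clock, i.e. shifted by
#' `true_lag_s`), and a ground-truth record of every latent quantity.
#'
#' Each episode places the left arm's packets at evenly spaced centres.
#' The right arm's packet centres interpolate, with weight `coupling`,
#' between a copy of the left layout and an independently drawn layout,
#' and its carrier phases get jitter with circular SD
#' `(1 - coupling) * pi`; so `coupling = 1` gives phase-locked arms and
#' `coupling = 0` arms whose movements share no consistent timing or
#' phase. Both layouts keep packets separated by more than the 50 ms merge
#' gap, so ground-truth counts stay recoverable at any coupling. Claps are
#' half-sine spikes shared by both arms inside `clap_window`.
#'
#' Identical configs (including `rng_seed`) give bit-identical output.
#'
#' @param config a [session_config()].
#' @return A list with components `left`, `right` ([accel_ts()]),
#'   `video_track` ([annotation_track()] on the video clock) and `truth`
#'   (list: `true_lag_s`, `clap_times`, per-episode table `episodes` with
#'   packet counts and conditions, `packets` per-episode packet timing, and
#'   `n_movements_total`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(config$rng_seed, {
    mk_noise <- function() list(ax = stats::rnorm(n, 0, config$noise_sd),
                                ay = stats::rnorm(n, 0, config$noise_sd),
                                az = stats::rnorm(n, 0, config$noise_sd) +
                                  config$gravity_offset)
    left <- mk_noise()
    right <- mk_noise()

    # claps: aperiodically spaced inside the window (1 s inset). Irregular
    # spacing matters: a periodic clap train aligns with itself shifted by
    # one clap, which would defeat the lag search
    clap_dur <- 0.12
    clap_onsets <- numeric(0)
    if (config$n_claps > 0) {
      lo <- config$clap_window[1] + 1
      hi <- config$clap_window[2] - 1 - clap_dur
      clap_onsets <- sort(random_packet_layout(config$n_claps, lo, hi, 1.5))
      for (c0 in clap_onsets) {
        inside <- t >= c0 & t <= c0 + clap_dur
        pulse <- config$clap_amplitude * sin(pi * (t[inside] - c0) / clap_dur)
        left$az[inside] <- left$az[inside] + pulse
        left$ax[inside] <- left$ax[inside] + 0.4 * pulse
        right$az[inside] <- right$az[inside] + pulse
        right$ax[inside] <- right$ax[inside] + 0.4 * pulse
      }
    }

    # episodes: per-episode substream so each episode is reproducible.
    # A packet is a circular (quadrature) oscillation on the two
    # gravity-orthogonal axes: two carrier cycles of burst_freq_hz under a
    # raised-cosine envelope. Its acceleration magnitude is a single
    # smooth bump, so one packet is exactly one detectable movement.
    packets <- list()
    for (i in seq_along(config$episodes)) {
      e <- config$episodes[[i]]
      half <- 1 / e$burst_freq_hz  # 2 carrier cycles per packet
      min_sep <- 2 * half + 0.12   # packet width + >50 ms inter-packet gap
      lo <- e$onset_s + half
      hi <- e$offset_s - half
      if (hi < lo) lo <- hi <- (e$onset_s + e$offset_s) / 2
      centers_l <- if (e$n_movements == 1) (lo + hi) / 2 else
        seq(lo, hi, length.out = e$n_movements)
      if (e$n_movements > 1 && (centers_l[2] - centers_l[1]) < min_sep)
        warning(sprintf(
          "episode %d: packets closer than packet width + 120 ms; ground-truth counts may merge", i))
      ep <- with_seed(episode_seed(config$rng_seed, i), {
        phase_l <- stats::runif(e$n_movements, 0, 2 * pi)
        phase_jit <- stats::rnorm(e$n_movements, 0, (1 - e$coupling) * pi)
        # right-arm packet times interpolate between a copy of the left
        # layout (coupling = 1) and an independently drawn layout
        # (coupling = 0); both respect min_sep, so any blend does too
        indep <- sort(random_packet_layout(e$n_movements, lo, hi, min_sep))
        centers_r <- e$coupling * centers_l + (1 - e$coupling) * indep
        data.frame(center_left = centers_l, center_right = centers_r,
                   phase_left = phase_l %% (2 * pi),
                   phase_right = (phase_l + phase_jit) %% (2 * pi))
      })
      add_packets <- function(arm, centers, phases) {
        for (k in seq_along(centers)) {
          env <- packet_envelope(t, centers[k], half)
          arg <- 2 * pi * e$burst_freq_hz * (t - centers[k]) + phases[k]
          arm$ax <- arm$ax + e$amplitude * env * sin(arg)
          arm$ay <- arm$ay + e$amplitude * env * cos(arg)
        }
        arm
      }
      left <- add_packets(left, ep$center_left, ep$phase_left)
      right <- add_packets(right, ep$center_right, ep$phase_right)
      packets[[i]] <- ep
    }

    drop_mask <- function() {
      m <- rep(FALSE, n)
      if (config$dropout_rate > 0)
        m[sample.int(n, round(config$dropout_rate * n))] <- TRUE
      m
    }
    miss_l <- drop_mask()
    miss_r <- drop_mask()
    left_ts <- accel_ts(t, left$ax, left$ay, left$az, fs, miss_l)
    right_ts <- accel_ts(t, right$ax, right$ay, right$az, fs, miss_r)

    ep_df <- if (length(config$episodes)) {
      do.call(rbind, lapply(config$episodes, function(e)
        data.frame(onset_s = e$onset_s, offset_s = e$offset_s,
                   burst_freq_hz = e$burst_freq_hz,
                   n_movements = e$n_movements, coupling = e$coupling,
                   condition = e$condition, stringsAsFactors = FALSE)))
    } else {
      data.frame(onset_s = numeric(0), offset_s = numeric(0),
                 burst_freq_hz = numeric(0), n_movements = integer(0),
                 coupling = numeric(0), condition = character(0))
    }

    lag <- config$true_lag_s
    video_track <- annotation_track(
      tier = c(rep("CLAP", length(clap_onsets)), rep("RATTLING", nrow(ep_df))),
      onset_s = c(clap_onsets + lag, ep_df$onset_s + lag),
      offset_s = c(clap_onsets + clap_dur + lag, ep_df$offset_s + lag),
      label = c(rep(NA_character_, length(clap_onsets)), ep_df$condition))

    list(left = left_ts, right = right_ts, video_track = video_track,
         truth = list(true_lag_s = lag,
                      clap_times = clap_onsets + clap_dur / 2,
                      clap_dur_s = clap_dur,
                      episodes = ep_df, packets = packets,
                      n_movements_total = sum(ep_df$n_movements)))
  })
}

#' Build a study-like session configuration
#'
#' Convenience wrapper that lays out a session resembling the recorded play
#' visits: episodes of a few seconds separated by pauses, burst carrier
#' frequencies of 1.5–2.5 Hz, movement counts matched to the packet rate
#' (so the resulting rattling frequency falls in the observed 0.5–2.5 Hz
#' range), and alternating maternal-rhythm conditions. All layout
#' randomness derives from `seed`; the returned config carries the same
#' seed, so sessions are fully reproducible.
#'
#' @param seed integer seed for both layout and sample noise.
#' @param coupling left-right coupling passed to every episode.
#' @param n_episodes number of rattling episodes.
#' @param duration_s session length in seconds.
#' @param episode_dur_s typical episode duration in seconds.
#' @param movement_density fraction of the maximal packet packing used for
#'   `n_movements`. Infants pause between shake bouts, so episodes are not
#'   wall-to-wall movement; 0.6 reproduces movement rates around 0.5-1 Hz
#'   and leaves the uncoupled arms genuinely uncoupled (at density 1 both
#'   arms' movement trains become near-periodic at the same rate, which is
#'   itself a bimanual coupling no layout randomisation can remove).
#' @param true_lag_s video-minus-sensor offset in seconds.
#' @param first_episode_s start of the first episode (after the clap window).
#' @param ... further arguments passed to [session_config()].
#' @return A [session_config()].
#' @export
study_session_config <- function(seed, coupling = 1, n_episodes = 8,
                                 duration_s = 300, episode_dur_s = 4,
                                 movement_density = 0.6,
                                 true_lag_s = 0, first_episode_s = 25, ...) {
  with_seed(abs(seed) %% 2147483000L + 1L, {
    durs <- episode_dur_s * stats::runif(n_episodes, 0.8, 1.2)
    # split the remaining free time into inter-episode pauses by
    # stick-breaking, so the layout always fits the session
    free <- duration_s - first_episode_s - 2 - sum(durs)
    if (free < 0.5 * n_episodes) stop("episodes do not fit in the session")
    u <- stats::runif(n_episodes)
    gaps <- free * u / sum(u)
    episodes <- vector("list", n_episodes)
    onset <- first_episode_s
    for (i in seq_len(n_episodes)) {
      dur <- durs[i]
      freq <- stats::runif(1, 1.5, 2.5)
      packet <- 2 / freq  # two carrier cycles
      n_max <- max(1L, 1L + floor((dur - packet - 0.1) / (packet + 0.12)))
      n_mov <- max(1L, as.integer(round(movement_density * n_max)))
      episodes[[i]] <- episode_spec(
        onset_s = onset, offset_s = onset + dur, burst_freq_hz = freq,
        n_movements = n_mov, coupling = coupling,
        condition = if (i %% 2 == 0) "MOTHER_PROVIDING" else "MOTHER_NOT_PROVIDING")
      onset <- onset + dur + gaps[i]
    }
    session_config(duration_s = duration_s, episodes = episodes,
                   true_lag_s = true_lag_s,
                   rng_seed = abs(seed) %% 2147483000L + 1L, ...)
  })
}
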