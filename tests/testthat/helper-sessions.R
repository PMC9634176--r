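# shared fixture builders: everything is generated in code at test time

# magnitude series straight from a value vector
mk_mag <- function(values, fs = 60, provenance = "SMOOTHED") {
  magnitude_series((seq_along(values) - 1) / fs, values, fs, provenance)
}

# accel series on a uniform grid from axis vectors
mk_accel <- function(ax, ay = NULL, az = NULL, fs = 60, missing = NULL) {
  n <- length(ax)
  if (is.null(ay)) ay <- numeric(n)
  if (is.null(az)) az <- numeric(n)
  accel_ts((seq_len(n) - 1) / fs, ax, ay, az, fs, missing)
}

# compact study-like session used across modules: 90 s, 6 episodes
test_session <- function(seed, coupling = 1, ...) {
  cfg <- study_session_config(seed, coupling = coupling, n_episodes = 6,
                              duration_s = 90, episode_dur_s = 5, ...)
  list(cfg = cfg, ses = generate_session(cfg))
}

# run a session through preprocessing and episode segmentation on the
# known true lag (bypassing clap sync where it is not under test)
joined_arms <- function(ses, cfg, condition = "ALL") {
  ml <- preprocess_sensor(ses$left)
  mr <- preprocess_sensor(ses$right)
  al <- align_track(ses$video_track, cfg$true_lag_s,
                    extent_s = cfg$duration_s)
  list(left = segment_episodes(ml, al, condition),
       right = segment_episodes(mr, al, condition))
}

# a random ~30%-coverage rattling track: 225 non-overlapping 2 s episodes
# over a 1500 s extent
rand_rattling_track <- function(seed, n_int = 225, len = 2, extent = 1500) {
  withr::with_seed(seed, {
    on <- sort(stats::runif(n_int, 0, extent - len - 1))
    for (i in 2:n_int) on[i] <- max(on[i], on[i - 1] + len + 0.5)
    annotation_track(rep("RATTLING", n_int), on, on + len,
                     "MOTHER_PROVIDING")
  })
}

# independent brute-force recurrence-profile oracle (plain loops)
brute_dcrp <- function(x, y, fs, window_s) {
  L <- round(window_s * fs)
  nx <- length(x); ny <- length(y)
  d <- min(sum(x), sum(y))
  vapply((-L):L, function(l) {
    lo <- max(1, 1 - l); hi <- min(nx, ny - l)
    if (hi < lo) return(0)
    sum(x[lo:hi] * y[(lo + l):(hi + l)]) / d
  }, 0)
}
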