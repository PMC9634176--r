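test_that("segment_episodes joins episode slices in order", {
  withr::local_seed(2)
  m <- mk_mag(abs(rnorm(600)) + 1)
  tr <- annotation_track(c("RATTLING", "RATTLING"), c(1, 4), c(2, 6),
                         c("MOTHER_PROVIDING", "MOTHER_NOT_PROVIDING"))
  j <- segment_episodes(m, tr)
  expect_equal(j$n_episodes, 2)
  expect_length(j$acc, 180)
  expect_equal(j$boundaries$start_idx, c(1, 61))
  expect_equal(j$boundaries$end_idx, c(60, 180))
  expect_equal(j$acc[1:60], m$acc[m$t >= 1 & m$t < 2])

  one <- segment_episodes(m, tr, "MOTHER_PROVIDING")
  expect_equal(one$n_episodes, 1)
  expect_equal(one$acc, m$acc[m$t >= 1 & m$t < 2])

  none <- segment_episodes(m, annotation_track("CLAP", 0.1, 0.3, NA))
  expect_equal(none$n_episodes, 0)
  expect_length(none$acc, 0)
})

test_that("noise-free sessions yield exact ground-truth movement counts", {
  for (seed in c(31, 32, 33)) {
    ts <- test_session(seed, noise_sd = 0, clap_amplitude = 2)
    j <- joined_arms(ts$ses, ts$cfg)
    cm <- count_movements(j$left, j$right)
    expect_equal(cm$n_movements, ts$ses$truth$n_movements_total)
    expect_equal(cm$per_episode_counts, ts$ses$truth$episodes$n_movements)
  }
})

test_that("movements 30 ms apart merge; a flat episode counts zero", {
  seg <- c(rep(0, 30), 9, 9, 0, 0, 9, 9, rep(0, 30))  # 2-sample gap
  m <- mk_mag(seg)
  tr <- annotation_track("RATTLING", 0, length(seg) / 60, "MOTHER_PROVIDING")
  j <- segment_episodes(m, tr)
  expect_equal(count_movements(j)$n_movements, 1)

  flat <- mk_mag(rep(1, 120))
  jf <- segment_episodes(flat, annotation_track("RATTLING", 0, 2,
                                                "MOTHER_PROVIDING"))
  expect_message(cf <- count_movements(jf), "zero-variance")
  expect_equal(cf$n_movements, 0)
  expect_equal(cf$zero_variance_episodes, 1L)
})

test_that("both-arm union counts a bimanual movement once", {
  base <- rep(0, 200)
  l <- base; l[50:60] <- 9
  r <- base; r[55:65] <- 9   # overlapping supra intervals
  tr <- annotation_track("RATTLING", 0, 200 / 60, "MOTHER_PROVIDING")
  jl <- segment_episodes(mk_mag(l), tr)
  jr <- segment_episodes(mk_mag(r), tr)
  expect_equal(count_movements(jl, jr)$n_movements, 1)
  expect_equal(count_movements(jl, jr, per_arm = TRUE)$n_movements, 2)
  # disjoint intervals count twice even under union
  r2 <- base; r2[120:130] <- 9
  jr2 <- segment_episodes(mk_mag(r2), tr)
  expect_equal(count_movements(jl, jr2)$n_movements, 2)
})

test_that("default-noise counts stay within 10% of truth across seeds", {
  # full study-scale visits (~25-30 movements), where a 10% bound is
  # meaningful; at a dozen movements it would be sub-integer
  errs <- vapply(1:20, function(seed) {
    cfg <- study_session_config(seed + 100, n_episodes = 15)
    ses <- generate_session(cfg)
    j <- joined_arms(ses, cfg)
    cm <- count_movements(j$left, j$right)
    abs(cm$n_movements - ses$truth$n_movements_total) /
      ses$truth$n_movements_total
  }, 0)
  expect_true(all(errs <= 0.10))
})

test_that("visit metrics compute frequency and apply the 2.5 Hz rule", {
  # 10 movements over 8 s of annotated rattling -> 1.25 Hz
  mk_joined <- function(n_ep_movs, durs) {
    b <- data.frame(onset_s = cumsum(c(0, durs[-length(durs)])) ,
                    offset_s = cumsum(durs), condition = "ALL",
                    start_idx = 1, end_idx = 2)
    structure(list(acc = numeric(10), fs = 60, boundaries = b,
                   n_episodes = length(durs)), class = "joined_series")
  }
  j <- mk_joined(durs = c(3, 5))
  cnt <- list(n_movements = 10, per_episode_counts = c(4L, 6L),
              zero_variance_episodes = integer(0))
  vm <- visit_metrics(j, cnt, visit_id = "v1")
  expect_equal(vm$rattling_freq_hz, 1.25)
  expect_false(vm$excluded)
  expect_equal(vm$mean_episode_dur_s, 4)
  expect_equal(vm$n_movements, 10)

  # 26 movements over 10 s -> 2.6 Hz, excluded
  j2 <- mk_joined(durs = c(4, 6))
  cnt2 <- list(n_movements = 26, per_episode_counts = c(10L, 16L),
               zero_variance_episodes = integer(0))
  expect_true(visit_metrics(j2, cnt2)$excluded)

  # episodes of 1 s and 3 s -> mean duration 2 s
  j3 <- mk_joined(durs = c(1, 3))
  cnt3 <- list(n_movements = 4, per_episode_counts = c(2L, 2L),
               zero_variance_episodes = integer(0))
  expect_equal(visit_metrics(j3, cnt3)$mean_episode_dur_s, 2)

  # re-coding filters
  vm4 <- visit_metrics(j, cnt, min_episodes_per_visit = 8)
  expect_true(vm4$below_min_episodes)
  vm5 <- visit_metrics(j, cnt, min_movements_per_episode = 5)
  expect_equal(vm5$n_episodes, 1)
  expect_equal(vm5$n_movements, 6)
  expect_error(visit_metrics(j, list(n_movements = 0,
                                     per_episode_counts = c(0L, 0L)),
                             min_movements_per_episode = 1),
               "no episodes survive")
})

test_that("condition-filtered counts partition the ALL counts", {
  for (seed in c(41, 42)) {
    ts <- test_session(seed)
    j_all <- joined_arms(ts$ses, ts$cfg, "ALL")
    j_np <- joined_arms(ts$ses, ts$cfg, "MOTHER_NOT_PROVIDING")
    j_p <- joined_arms(ts$ses, ts$cfg, "MOTHER_PROVIDING")
    n_all <- count_movements(j_all$left, j_all$right)$n_movements
    n_np <- count_movements(j_np$left, j_np$right)$n_movements
    n_p <- count_movements(j_p$left, j_p$right)$n_movements
    expect_equal(n_all, n_np + n_p)
  }
})

test_that("rattling frequency of clean sessions matches ground truth", {
  ts <- test_session(55, noise_sd = 0, clap_amplitude = 2)
  j <- joined_arms(ts$ses, ts$cfg)
  cm <- count_movements(j$left, j$right)
  vm <- visit_metrics(j$left, cm)
  total_dur <- sum(ts$ses$truth$episodes$offset_s -
                     ts$ses$truth$episodes$onset_s)
  expect_equal(vm$rattling_freq_hz,
               ts$ses$truth$n_movements_total / total_dur,
               tolerance = 1 / total_dur)
})
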