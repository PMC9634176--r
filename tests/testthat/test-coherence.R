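test_that("Morlet CWT peaks at the frequency of a pure sinusoid", {
  fs <- 60
  t <- (0:(20 * fs - 1)) / fs
  cw <- morlet_cwt(sin(2 * pi * 1 * t), fs = fs)
  pow <- rowMeans(Mod(cw$coeffs)^2)
  f_peak <- cw$freqs[which.max(pow)]
  # closed-form Morlet response peaks at f * (w0 + sqrt(2 + w0^2)) / (2 w0)
  # = 1.014 f for w0 = 6; allow one dyadic scale step (2^(1/12))
  expect_lt(abs(log2(f_peak / 1.014)), 1 / 12 + 1e-9)
  expect_true(all(diff(cw$freqs) < 0))
  expect_equal(dim(cw$coeffs), c(length(cw$freqs), length(t)))
})

test_that("a constant input has near-zero wavelet power everywhere", {
  cw <- morlet_cwt(rep(2.5, 600), fs = 60)
  expect_lt(max(Mod(cw$coeffs)), 1e-10)
})

test_that("inputs shorter than two low-frequency periods are flagged", {
  expect_warning(morlet_cwt(rnorm(200), fs = 60), "shorter than two periods")
  expect_error(morlet_cwt(numeric(1), fs = 60), "too short")
})

test_that("any nonconstant series is fully coherent with itself", {
  ses <- test_session(61)$ses
  m <- preprocess_sensor(ses$left)
  wc <- wavelet_coherence(m, m)
  expect_equal(wc$band_mean, 1, tolerance = 1e-9)
  expect_true(all(abs(wc$wc - 1) < 1e-9))
})

test_that("constant phase shifts do not reduce coherence", {
  fs <- 60
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t)
  y <- sin(2 * pi * 1 * t + pi / 2)
  wc <- wavelet_coherence(x, y, fs = fs)
  expect_gt(wc$band_mean, 0.99)
})

test_that("coherence input contracts are enforced", {
  expect_error(wavelet_coherence(rnorm(100), rnorm(99), fs = 60),
               "lengths differ")
  expect_error(wavelet_coherence(rep(1, 300), rnorm(300), fs = 60),
               "constant input")
})

test_that("coherence is symmetric and invariant to positive rescaling", {
  withr::local_seed(19)
  x <- rnorm(900) + 1
  y <- rnorm(900) + 1
  a <- wavelet_coherence(x, y, fs = 60)
  b <- wavelet_coherence(y, x, fs = 60)
  expect_lt(max(abs(a$wc - b$wc)), 1e-9)
  c2 <- wavelet_coherence(3.2 * x, y / 7, fs = 60)
  expect_lt(max(abs(a$wc - c2$wc)), 1e-9)
})

test_that("coherence stays inside [0, 1] for random input pairs", {
  withr::local_seed(23)
  for (rep in 1:15) {
    wc <- wavelet_coherence(rnorm(400) + 1, rnorm(400) + 1, fs = 60,
                            f_min = 0.5)
    expect_gte(wc$raw_range[1], -1e-9)
    expect_lte(wc$raw_range[2], 1 + 1e-9)
  }
})

test_that("without smoothing the coherence degenerates to 1 everywhere", {
  # known algebraic degeneracy; guards against a silently disabled smoother
  withr::local_seed(29)
  wc <- wavelet_coherence(rnorm(600) + 1, rnorm(600) + 1, fs = 60,
                          smoothing = FALSE)
  expect_true(all(abs(wc$wc - 1) < 1e-6))
  expect_equal(wc$band_mean, 1, tolerance = 1e-9)
})

test_that("band averaging selects rows and honours the COI option", {
  wc <- wavelet_coherence(rnorm(600) + 1, rnorm(600) + 1, fs = 60)
  fake <- wc
  in_band <- fake$freqs >= 0.5 & fake$freqs <= 2.5
  fake$wc[in_band, ] <- 1
  fake$wc[!in_band, ] <- 0
  expect_equal(band_average(fake), 1)
  fake$wc[] <- 0
  expect_equal(band_average(fake), 0)
  # half the band rows at 1, half at 0 -> 0.5
  rows <- which(in_band)
  fake$wc[rows[seq_len(floor(length(rows) / 2))], ] <- 1
  expect_equal(band_average(fake),
               floor(length(rows) / 2) / length(rows))
  expect_error(band_average(wc, 10, 20), "no scale rows")
  expect_lt(band_average(wc, coi_exclude = TRUE), 1)
})

test_that("the compiled band-mean kernel matches the R reference path", {
  withr::local_seed(31)
  n <- 700; fs <- 60
  x <- rnorm(n) + 1; y <- rnorm(n) + 1
  geom <- rattlewave:::wc_geometry(n, fs)
  h <- geom$boxw %/% 2L
  rows <- which(geom$freqs >= 0.5 & geom$freqs <= 2.5)
  keep <- (min(rows) - h):(max(rows) + h)
  sub <- rattlewave:::wc_geometry(n, fs, scales = geom$scales[keep],
                                  pad_mult = 2)
  br <- which(sub$freqs >= 0.5 & sub$freqs <= 2.5)
  raw <- rattlewave:::wc_raw_matrix(x, y, sub, smoothing = TRUE)
  r_ref <- mean(pmin(pmax(raw[, br, drop = FALSE], 0), 1))
  cpp <- rattlewave:::.wc_band_mean_cpp(x, y, sub$filters, sub$gmult,
                                        1 / sub$scales, br - 1L, sub$boxw)
  expect_equal(cpp, r_ref, tolerance = 1e-12)
})

test_that("self-coherence beats every permutation draw", {
  withr::local_seed(37)
  x <- rnorm(800) + 1
  sn <- surrogate_null(x, x, n_iter = 100, seed = 0, fs = 60)
  expect_equal(sn$observed, 1, tolerance = 1e-6)
  expect_true(all(sn$null_values < sn$observed))
  expect_lt(sn$p_value, 0.05)
  expect_length(sn$null_values, 100)
  expect_error(surrogate_null(x, x, n_iter = 0, fs = 60), "at least 1")
})

test_that("independent noise sits inside its own surrogate null", {
  hits <- vapply(1:6, function(seed) {
    withr::with_seed(seed, {
      x <- rnorm(1200) + 1
      y <- rnorm(1200) + 1
      sn <- surrogate_null(x, y, n_iter = 200, seed = seed, fs = 60)
      q <- stats::quantile(sn$null_values, c(0.025, 0.975))
      expect_lt(sn$observed, 0.5)
      sn$observed >= q[1] && sn$observed <= q[2]
    })
  }, TRUE)
  expect_gte(sum(hits), 5)
})

test_that("band coherence is nondecreasing in the coupling parameter", {
  means <- vapply(c(0, 0.5, 1), function(cp) {
    mean(vapply(c(71, 72, 73), function(seed) {
      ts <- test_session(seed, coupling = cp)
      j <- joined_arms(ts$ses, ts$cfg)
      wavelet_coherence(j$left$acc, j$right$acc, fs = 60)$band_mean
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1] + 0.2)
})

test_that("phase-locked identical-frequency sessions are near-coherent", {
  ts <- test_session(81, coupling = 1)
  j <- joined_arms(ts$ses, ts$cfg)
  wc <- wavelet_coherence(j$left$acc, j$right$acc, fs = 60)
  expect_gt(wc$band_mean, 0.8)
})

test_that("group-level shuffle comparison behaves across regimes", {
  expect_error(group_null_test(1, 1), "at least 2")
  same <- c(0.4, 0.5, 0.6, 0.55)
  r <- group_null_test(same, same)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_silent(group_null_test(same, same))
  expect_warning(r2 <- group_null_test(same + 1, same), "degenerate")
  expect_true(r2$degenerate)
  expect_true(is.na(r2$t_stat))
  # coupled sessions: observed clearly above their null means
  obs <- null_m <- numeric(6)
  for (i in 1:6) {
    ts <- test_session(90 + i, coupling = 1)
    j <- joined_arms(ts$ses, ts$cfg)
    sn <- surrogate_null(j$left$acc, j$right$acc, n_iter = 100,
                         seed = i, fs = 60)
    obs[i] <- sn$observed
    null_m[i] <- mean(sn$null_values)
  }
  r3 <- group_null_test(obs, null_m)
  expect_gt(r3$t_stat, 0)
  expect_lt(r3$p_value, 0.05)
})

test_that("single-hand spectra localise burst frequency content", {
  fs <- 60
  t <- (0:(40 * fs - 1)) / fs
  # 2.5 Hz bursts: windowed oscillation every 2 s over a baseline
  env <- ifelse((t %% 2) < 0.8, 0.5 * (1 - cos(2 * pi * (t %% 2) / 0.8)), 0)
  m <- mk_mag(1 + env * sin(2 * pi * 2.5 * t) + 0.02 * rnorm(length(t)))
  sp <- single_hand_spectrum(m)
  f_peak <- sp$freq_hz[which.max(sp$power)]
  expect_gte(f_peak, 2)
  expect_lte(f_peak, 3)
  # doubling the amplitude quadruples the power
  sp2 <- single_hand_spectrum(1 + 2 * (m$acc - 1), fs = fs)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-9)
  # constant input: flat and essentially zero
  spc <- single_hand_spectrum(rep(3, 600), fs = 60)
  expect_lt(max(spc$power), 1e-18)
})
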