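# build a long table with planted per-timepoint means
sim_table <- function(seed, n_subj = 30, means = c(0, 0, 0, 0), sd = 1,
                      conditions = "ALL") {
  withr::with_seed(seed, {
    tps <- paste0("T", seq_along(means))
    g <- expand.grid(subject_id = sprintf("s%02d", 1:n_subj),
                     timepoint = tps, condition = conditions,
                     stringsAsFactors = FALSE)
    subj_eff <- stats::rnorm(n_subj, 0, sd / 2)
    names(subj_eff) <- sprintf("s%02d", 1:n_subj)
    g$value <- means[match(g$timepoint, tps)] + subj_eff[g$subject_id] +
      stats::rnorm(nrow(g), 0, sd)
    longitudinal_table(g$subject_id, g$timepoint, g$condition,
                       "metric", g$value)
  })
}

test_that("longitudinal tables reject duplicate cells", {
  expect_error(longitudinal_table(c("a", "a"), c("T1", "T1"),
                                  c("ALL", "ALL"), c("m", "m"), c(1, 2)),
               "duplicate")
})

test_that("a planted age effect is detected with high power", {
  hits <- vapply(1:20, function(seed) {
    tab <- sim_table(seed, means = c(0, 0.5, 1, 1.5))
    fit <- fit_repeated_effects(tab, "metric", factors = "timepoint")
    fit$effects$p[fit$effects$factor == "timepoint"] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("a constant metric shows no age effect", {
  tab <- sim_table(1, means = c(0, 0, 0, 0), sd = 0)
  tab$value <- 3
  fit <- fit_repeated_effects(tab, "metric", factors = "timepoint")
  expect_equal(fit$effects$wald_chisq, 0, tolerance = 1e-6)
  expect_equal(fit$effects$p, 1, tolerance = 1e-6)
})

test_that("type-I error of the age test stays near nominal", {
  pvals <- vapply(1:200, function(seed) {
    tab <- sim_table(seed + 1000, n_subj = 150)
    fit <- fit_repeated_effects(tab, "metric", factors = "timepoint")
    fit$effects$p[1]
  }, 0)
  expect_lte(mean(pvals < 0.05), 0.075)
})

test_that("pairwise contrasts carry Bonferroni-adjusted p-values", {
  tab <- sim_table(3, means = c(0, 0.4, 0.8, 1.2))
  fit <- fit_repeated_effects(tab, "metric", factors = "timepoint")
  pw <- fit$pairwise
  expect_equal(nrow(pw), choose(4, 2))
  expect_equal(pw$p_adj, pmin(1, pw$p * choose(4, 2)))
  # largest separation: T1 vs T4
  expect_lt(pw$p_adj[pw$level1 == "T1" & pw$level2 == "T4"], 0.05)
})

test_that("both factors and their interaction are testable", {
  withr::with_seed(5, {
    g <- expand.grid(subject_id = sprintf("s%02d", 1:30),
                     timepoint = paste0("T", 1:4),
                     condition = c("MOTHER_NOT_PROVIDING", "MOTHER_PROVIDING"),
                     stringsAsFactors = FALSE)
    g$value <- 0.8 * (g$condition == "MOTHER_PROVIDING") + rnorm(nrow(g))
    tab <- longitudinal_table(g$subject_id, g$timepoint, g$condition,
                              "coherence", g$value)
  })
  fit <- fit_repeated_effects(tab, "coherence")
  expect_setequal(fit$effects$factor,
                  c("timepoint", "condition", "timepoint:condition"))
  expect_lt(fit$effects$p[fit$effects$factor == "condition"], 0.05)
  expect_gt(fit$effects$p[fit$effects$factor == "timepoint"], 0.05)
  expect_equal(sum(fit$pairwise$factor == "condition"), 1)
})

test_that("independence-GEE matches glm with cluster-robust covariance", {
  skip_if_not_installed("sandwich")
  tab <- sim_table(7, n_subj = 20, means = c(0, 0.3, 0.6, 0.9))
  fit <- fit_repeated_effects(tab, "metric", factors = "timepoint",
                              corstr = "independence")
  df <- as.data.frame(tab)
  df$timepoint <- factor(df$timepoint)
  g <- stats::glm(value ~ timepoint, data = df)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  Vcl <- sandwich::vcovCL(g, cluster = df$subject_id, type = "HC0",
                          cadjust = FALSE)
  expect_equal(unname(fit$vcov_robust), unname(Vcl), tolerance = 1e-6)
})

test_that("poisson-family counts recover a planted rate increase", {
  withr::with_seed(11, {
    g <- expand.grid(subject_id = sprintf("s%02d", 1:25),
                     timepoint = paste0("T", 1:4), stringsAsFactors = FALSE)
    lam <- c(T1 = 18, T2 = 39, T3 = 63, T4 = 84)  # movement-count scale
    g$value <- rpois(nrow(g), lam[g$timepoint])
    tab <- longitudinal_table(g$subject_id, g$timepoint, "ALL",
                              "n_movements", g$value)
  })
  fit <- fit_repeated_effects(tab, "n_movements", factors = "timepoint",
                              family = "poisson")
  expect_lt(fit$effects$p[1], 0.001)
  # log-link coefficients recover the rate ratios
  expect_equal(unname(fit$coefficients[2]), log(39 / 18), tolerance = 0.15)
})

test_that("two-timepoint marginal fit agrees with a paired t-test", {
  tab <- sim_table(13, means = c(0, 0.6, 0, 0)[1:2])
  fit <- fit_repeated_effects(tab, "metric", factors = "timepoint")
  df <- as.data.frame(tab)
  wide <- stats::reshape(df[, c("subject_id", "timepoint", "value")],
                         idvar = "subject_id", timevar = "timepoint",
                         direction = "wide")
  tt <- stats::t.test(wide$value.T2, wide$value.T1, paired = TRUE)
  expect_equal(sign(unname(fit$coefficients[2])),
               sign(unname(tt$estimate)))
  expect_equal((fit$pairwise$p < 0.05), (tt$p.value < 0.05))
})

test_that("errors name missing levels and degenerate designs", {
  tab <- sim_table(15)
  expect_error(fit_repeated_effects(tab, "nope"), "no rows")
  one_tp <- as.data.frame(tab)
  one_tp <- one_tp[one_tp$timepoint == "T1", ]
  expect_error(fit_repeated_effects(one_tp, "metric", factors = "timepoint"),
               "fewer than 2 levels")
})

test_that("kappa is 1 for identical coders and near 0 for chance", {
  tr <- annotation_track(rep("RATTLING", 3), c(1, 5, 9), c(2, 7, 12),
                         "MOTHER_PROVIDING")
  expect_equal(cohens_kappa(tr, tr), 1)

  # complementary coders agree nowhere
  a <- annotation_track("RATTLING", 0, 10, "MOTHER_PROVIDING")
  b <- annotation_track("RATTLING", 10, 20, "MOTHER_PROVIDING")
  expect_lte(cohens_kappa(a, b, extent_s = 20), 0)

  # independent ~30%-coverage tracks: |kappa| < 0.1 in every seed.
  # short episodes over a long recording keep the effective number of
  # independent frames high enough that chance kappa concentrates near 0
  ks <- vapply(1:20, function(s)
    cohens_kappa(rand_rattling_track(2 * s), rand_rattling_track(2 * s + 1),
                 extent_s = 1510), 0)
  expect_true(all(abs(ks) < 0.1))
})

test_that("kappa is symmetric and invariant to label swap", {
  withr::local_seed(17)
  a <- annotation_track(rep("RATTLING", 4), c(0, 10, 20, 30),
                        c(4, 13, 26, 33), "MOTHER_PROVIDING")
  b <- annotation_track(rep("RATTLING", 3), c(2, 11, 24), c(6, 15, 31),
                        "MOTHER_NOT_PROVIDING")
  k1 <- cohens_kappa(a, b, extent_s = 40)
  expect_equal(cohens_kappa(b, a, extent_s = 40), k1)
  # label swap: complement both rasters == swap 0/1 labels
  comp <- function(tr, extent) {
    r <- binarize_annotations(tr, "RATTLING", 25, extent)
    runs <- rle(r == 0)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    annotation_track(rep("RATTLING", sum(runs$values)),
                     (starts[runs$values] - 1) / 25,
                     ends[runs$values] / 25, "MOTHER_PROVIDING")
  }
  k2 <- cohens_kappa(comp(a, 40), comp(b, 40), extent_s = 40)
  expect_equal(k2, k1, tolerance = 1e-9)
})

test_that("kappa is undefined when both raters are constant and equal", {
  a <- annotation_track("RATTLING", 0, 10, "MOTHER_PROVIDING")
  expect_warning(k <- cohens_kappa(a, a, extent_s = 10), "undefined")
  expect_true(is.na(k))
})
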