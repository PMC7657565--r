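test_that("noiseless simulation and OLS invert each other", {
  s <- generate_session(schedule_spec("changing_up", n_rewarded_trials = 40), seed = 1)
  des <- build_fmri_design(s)
  eff <- c(reward_current = 0.4, reward_lag1 = -0.1, VS_left = 0.25)
  ts <- simulate_roi_bold(des, eff, noise_sd = 0)
  g <- fit_session_glm(ts, des, define_contrasts(0.257))
  b <- setNames(g$betas$estimate, g$betas$term)
  expect_equal(b[["reward_current"]], 0.4, tolerance = 1e-10)
  expect_equal(b[["reward_lag1"]], -0.1, tolerance = 1e-10)
  expect_equal(b[["VS_left"]], 0.25, tolerance = 1e-10)
  expect_equal(b[["RRE_outcome"]], 0, tolerance = 1e-10)
  expect_lt(g$sigma, 1e-9)
  # unknown effect names are rejected
  expect_error(simulate_roi_bold(des, c(bogus = 1)), "Unknown regressor")
  # fixed seed reproduces the series
  t1 <- simulate_roi_bold(des, eff, noise_sd = 1, seed = 3)
  t2 <- simulate_roi_bold(des, eff, noise_sd = 1, seed = 3)
  expect_identical(t1$bold, t2$bold)
})

test_that("session GLM z-statistics are calibrated under pure noise", {
  s <- generate_session(schedule_spec("stable"), seed = 14)
  des <- build_fmri_design(s)
  ctr <- define_contrasts(0.257)["sRPE"]
  n_hit <- 0
  n_seeds <- 300
  for (seed in seq_len(n_seeds)) {
    ts <- simulate_roi_bold(des, noise_sd = 1, ar1_coef = 0, seed = seed)
    z <- fit_session_glm(ts, des, ctr)$contrasts$z
    n_hit <- n_hit + (abs(z) < 1.96)
  }
  # ~95% coverage, allow 4 binomial SDs
  expect_gt(n_hit / n_seeds, 0.95 - 4 * sqrt(0.95 * 0.05 / n_seeds))
  expect_lt(n_hit / n_seeds, 0.95 + 4 * sqrt(0.95 * 0.05 / n_seeds))
})

test_that("injected contrast amplitudes are recovered without material bias", {
  s <- generate_session(schedule_spec("stable"), seed = 21)
  des <- build_fmri_design(s)
  w <- define_contrasts(0.257)$sRPE
  eff <- setNames(0.3 * w, names(w)) # beta pattern proportional to contrast
  truth <- fit_session_glm(
    simulate_roi_bold(des, eff, noise_sd = 0),
    des, define_contrasts(0.257)["sRPE"]
  )$contrasts$effect
  ests <- vapply(1:60, function(seed) {
    ts <- simulate_roi_bold(des, eff, noise_sd = 1, seed = 1000 + seed)
    fit_session_glm(ts, des, define_contrasts(0.257)["sRPE"])$contrasts$effect
  }, 0)
  expect_lt(abs(mean(ests) - truth) / truth, 0.05)
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  s <- generate_session(schedule_spec("stable", n_rewarded_trials = 30), seed = 4)
  des <- build_fmri_design(s)
  # duplicate a column to force aliasing
  des$design$VS_right <- des$design$VS_left
  ts <- simulate_roi_bold(des, noise_sd = 1, seed = 1)
  expect_warning(g <- fit_session_glm(ts, des), "rank deficient")
  expect_gt(length(g$dropped_cols), 0)
})

test_that("two-level combination weights sessions by precision", {
  # hand-built session table: subject A has one precise and one vague session
  tbl <- tibble::tibble(
    subject = c("a", "a", "b", "b"),
    session = c("a1", "a2", "b1", "b2"),
    contrast = "sRPE",
    effect = c(1.0, 3.0, 2.0, 2.4),
    se = c(0.1, 1.0, 0.5, 0.5)
  )
  g <- combine_levels(tbl)
  subj <- attr(g, "subject_effects")
  # precision-weighted mean for subject a: w = 100, 1
  expect_equal(
    subj$effect[subj$subject == "a"],
    (100 * 1 + 1 * 3) / 101,
    tolerance = 1e-12
  )
  expect_equal(subj$effect[subj$subject == "b"], 2.2)
  m <- mean(subj$effect)
  sdv <- sd(subj$effect)
  expect_equal(g$group_effect, m)
  expect_equal(g$t, m / (sdv / sqrt(2)), tolerance = 1e-12)
  expect_equal(g$df, 1)
  # degenerate identical subjects are flagged rather than reported as exact
  tbl2 <- tbl
  tbl2$effect <- 2
  g2 <- combine_levels(tbl2)
  expect_true(g2$flagged)
  expect_true(is.infinite(g2$t))
  # single subject is rejected
  expect_error(combine_levels(tbl[1:2, ]), ">= 2 subjects")
})

test_that("group calibration holds under a between-subject null", {
  set.seed(42)
  n_sig <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    tbl <- tibble::tibble(
      subject = rep(sprintf("s%d", 1:6), each = 2),
      session = sprintf("ses%d", 1:12),
      contrast = "c",
      effect = rnorm(12, 0, 1),
      se = runif(12, 0.5, 1.5)
    )
    n_sig <- n_sig + (combine_levels(tbl)$p < 0.05)
  }
  # subject means are not exactly unit-variance draws, but the t-test is
  # exact under normality: empirical size should straddle 5%
  expect_gt(n_sig / n_rep, 0.02)
  expect_lt(n_sig / n_rep, 0.09)
})

test_that("epoch extraction baselines, averages and splits by outcome", {
  tr <- 2.28
  n_vol <- 200
  time <- (0:(n_vol - 1)) * tr
  flat <- tibble::tibble(volume = 1:n_vol, time = time, bold = 0)
  attr(flat, "tr") <- tr
  onsets <- c(30, 100, 250)
  out <- extract_timecourse(flat, onsets, window_s = 12)
  expect_equal(out$epochs$epoch_mean, rep(0, 3))

  # constructed signal: one HRF per onset, amplitude = drops
  drops <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  onsets <- seq(30, by = 40, length.out = 9)
  sig <- convolve_events(onsets, drops, n_volumes = n_vol, tr = tr)
  ts <- tibble::tibble(volume = 1:n_vol, time = time, bold = sig * 100)
  attr(ts, "tr") <- tr
  out2 <- extract_timecourse(ts, onsets, split = drops)
  means <- tapply(out2$epochs$epoch_mean, out2$epochs$split, mean)
  expect_lt(means[["1"]], means[["2"]])
  expect_lt(means[["2"]], means[["3"]])
  expect_gt(means[["3"]], 0)

  # prediction-error-like signal: amplitude = drops - 2 gives suppressed
  # 1-drop and elevated 3-drop epochs
  sig3 <- convolve_events(onsets, drops - 2, n_volumes = n_vol, tr = tr)
  ts3 <- tibble::tibble(volume = 1:n_vol, time = time, bold = sig3 * 100)
  attr(ts3, "tr") <- tr
  out3 <- extract_timecourse(ts3, onsets, split = drops)
  means3 <- tapply(out3$epochs$epoch_mean, out3$epochs$split, mean)
  expect_lt(means3[["1"]], 0)
  expect_gt(means3[["3"]], 0)

  # epochs overrunning the scan are excluded and counted
  out4 <- extract_timecourse(ts, c(onsets, 1e5), split = c(drops, 1))
  expect_identical(out4$n_excluded, 1L)

  # the group test flags subject-consistent deviations
  et <- tibble::tibble(
    subject = rep(c("a", "b", "c"), each = 4),
    epoch_mean = rnorm(12, 2, 0.1)
  )
  gt <- epoch_group_test(et)
  expect_lt(gt$p, 0.01)
  expect_equal(gt$df, 2)
})
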