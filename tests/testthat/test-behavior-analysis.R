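test_that("the design matrix builds the regressors the models need", {
  s <- generate_session(schedule_spec("stable", n_rewarded_trials = 25), seed = 6)
  tr <- simulate_behavior(s, agent_params(), seed = 7)
  d <- build_behavior_design(tr, alpha = 0.257, zscore_scope = "none")
  # first 5 trials dropped for lack of reward history
  expect_true(all(d$trial > 5))
  # sre column equals the oracle recursion evaluated at each trial
  v <- oracle_rw(s$drops, 0.257, 2)
  expect_equal(d$sre, v[d$trial], tolerance = 1e-12)
  # lagged mode produces the shifted reward sequence
  dl <- build_behavior_design(tr, alpha = NULL, zscore_scope = "none")
  expect_equal(dl$r_lag1, s$drops[dl$trial - 1])
  expect_equal(dl$r_lag5, s$drops[dl$trial - 5])
  # z-scored design has unit-variance columns
  dz <- build_behavior_design(tr, alpha = 0.257)
  for (p in attr(dz, "predictors")) {
    expect_equal(mean(dz[[p]]), 0, tolerance = 1e-8)
    expect_equal(sd(dz[[p]]), 1, tolerance = 1e-8)
  }
})

test_that("attempts after an error carry no VS and no RRE", {
  s <- generate_session(schedule_spec("stable", n_rewarded_trials = 30), seed = 2)
  sloppy <- agent_params(lapse_coefs = c(
    intercept = qlogis(0.5), vs = 0, sre = 0,
    rre = 0, position = 0, trialno = 0
  ), p_error = 1)
  tr <- simulate_behavior(s, sloppy, seed = 11)
  d <- build_behavior_design(tr, alpha = 0.257, zscore_scope = "none")
  after_error <- d$attempt > 1
  expect_gt(sum(after_error), 0)
  expect_true(all(d$vs[after_error] == 0))
  expect_true(all(d$rre[after_error] == 0))
})

test_that("a constant-side session triggers the zero-variance warning", {
  s <- generate_session(
    schedule_spec("stable",
      n_rewarded_trials = 20,
      run_length_range = c(50, 50), p_offside = 0
    ),
    seed = 3
  )
  tr <- simulate_behavior(s, agent_params(), seed = 4)
  expect_warning(
    d <- build_behavior_design(tr, alpha = 0.257),
    "Zero-variance"
  )
  expect_false("vs" %in% attr(d, "predictors"))
})

test_that("the logistic fit recovers an intercept-only lapse rate", {
  ag <- agent_params(
    lapse_coefs = c(
      intercept = qlogis(0.1), vs = 0, sre = 0, rre = 0,
      position = 0, trialno = 0
    ),
    p_error = 0
  )
  trials <- tiny_cohort(
    n_subjects = 3, n_sessions = 4, n_trials = 150,
    agent = ag, seed = 21
  )
  d <- build_behavior_design(trials, alpha = 0.257)
  f <- fit_lapse_model(d, predictors = character(0))
  intercept <- f$coefficients$estimate[f$coefficients$term == "(Intercept)"]
  expect_equal(intercept, qlogis(0.1), tolerance = 0.25)
})

test_that("generative coefficient signs are recovered by the lapse fit", {
  ag <- agent_params() # vs +, sre -, trialno +
  n_ok_vs <- 0
  n_ok_sre <- 0
  n_reps <- 12
  for (r in seq_len(n_reps)) {
    trials <- tiny_cohort(
      n_subjects = 3, n_sessions = 3, n_trials = 150,
      agent = ag, seed = 300 + r
    )
    f <- fit_lapse_model(build_behavior_design(trials, alpha = 0.257))
    co <- f$coefficients
    n_ok_vs <- n_ok_vs + (co$estimate[co$term == "vs"] > 0)
    n_ok_sre <- n_ok_sre + (co$estimate[co$term == "sre"] < 0)
  }
  expect_gte(n_ok_vs, n_reps - 1)
  expect_gte(n_ok_sre, n_reps - 1)
})

test_that("the mixed-model route runs and agrees with aggregation on signs", {
  trials <- tiny_cohort(
    n_subjects = 3, n_sessions = 2, n_trials = 120,
    agent = agent_params(), seed = 77
  )
  d <- build_behavior_design(trials, alpha = 0.257)
  f_auto <- fit_lapse_model(d, method = "auto")
  expect_s3_class(f_auto, "rws_fit")
  expect_true(f_auto$method %in% c("glmer", "per_subject"))
  f_ps <- fit_lapse_model(d, method = "per_subject")
  # population VS coefficients from the two routes should agree in sign
  b1 <- f_auto$coefficients$estimate[f_auto$coefficients$term == "vs"]
  b2 <- f_ps$coefficients$estimate[f_ps$coefficients$term == "vs"]
  expect_identical(sign(b1), sign(b2))
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  mkfit <- function(ll, preds) {
    structure(
      list(
        logLik = ll, df_model = length(preds) + 1, n_obs = 100,
        predictors = preds
      ),
      class = "rws_fit"
    )
  }
  full <- mkfit(-120, c("a", "b"))
  same <- mkfit(-120, c("a", "b"))
  red <- mkfit(-121.92, c("a"))
  expect_equal(lr_test(full, same, df = 1)$chi2, 0)
  expect_equal(lr_test(full, same, df = 1)$p, 1)
  out <- lr_test(full, red)
  expect_equal(out$chi2, 3.84, tolerance = 1e-9)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$p, 0.05, tolerance = 0.01)
  # the 2-df variant used for the learning-rate-bearing sRE term
  red2 <- mkfit(-120 - 6.918 / 2, character(0))
  out2 <- lr_test(full, red2, df = 2)
  expect_equal(out2$p, 0.031, tolerance = 0.02)
  # reduced model must be nested
  other <- mkfit(-119, c("c"))
  expect_error(lr_test(full, other), "nested")
  # reduced likelihood above full is clipped to zero evidence
  expect_equal(lr_test(mkfit(-130, c("a", "b")), mkfit(-129, "a"), df = 1)$chi2, 0)
})

test_that("the truncated-RW inversion recovers the learning rate", {
  # noiseless inversion at the published-scale alpha
  b <- 0.6 * oracle_lag_weights(0.257)
  fit <- fit_truncated_rw(b)
  expect_equal(fit$alpha_hat, 0.257, tolerance = 1e-6)
  expect_equal(fit$scale_hat, 0.6, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-10)
  # negative scale is legitimate (lapse betas are negative)
  fit_neg <- fit_truncated_rw(-0.3 * oracle_lag_weights(0.42))
  expect_equal(fit_neg$alpha_hat, 0.42, tolerance = 1e-6)
  expect_equal(fit_neg$scale_hat, -0.3, tolerance = 1e-6)
  # one-trial memory
  expect_equal(fit_truncated_rw(c(0.8, 0, 0, 0, 0))$alpha_hat, 1)
  # degenerate all-zero weights are flagged
  z <- fit_truncated_rw(rep(0, 5))
  expect_true(z$flagged)
  expect_true(is.na(z$alpha_hat))
  expect_error(fit_truncated_rw(c(1, 2, 3)), "5 finite")
})

test_that("noisy truncated-RW fits match a dense brute-force oracle", {
  set.seed(99)
  errs <- numeric(50)
  for (i in 1:50) {
    b <- oracle_lag_weights(0.4) * -0.3 + rnorm(5, 0, 0.01)
    fit <- fit_truncated_rw(b)
    errs[i] <- abs(fit$alpha_hat - 0.4)
    if (i <= 5) {
      oracle <- oracle_rw_gridfit(b)
      expect_equal(fit$alpha_hat, unname(oracle["alpha"]), tolerance = 1e-3)
      expect_lte(fit$residual_norm, oracle["res"] + 1e-9)
    }
  }
  expect_lt(median(errs), 0.05)
})

test_that("the reward-history slope test behaves at its edges and under signal", {
  # constant betas: zero slope everywhere, flagged degenerate
  flat <- matrix(0.2, nrow = 4, ncol = 5)
  out <- reward_history_slope_test(flat)
  expect_equal(out$t, 0)
  expect_true(out$flagged)
  # clean linear decay with tiny jitter: strongly significant, df = n - 1
  set.seed(12)
  betas <- t(replicate(6, -0.1 * (1:5) + rnorm(5, 0, 0.002)))
  out2 <- reward_history_slope_test(betas)
  expect_equal(out2$df, 5)
  expect_lt(out2$p, 0.001)
  expect_equal(out2$mean_slope, -0.1, tolerance = 0.01)
  # subjects with missing betas are dropped with a warning
  betas[2, 3] <- NA
  expect_warning(out3 <- reward_history_slope_test(betas), "excluded")
  expect_equal(out3$df, 4)
})

test_that("the RT model fits a gamma/log-link with sensible intercepts", {
  trials <- tiny_cohort(
    n_subjects = 3, n_sessions = 2, n_trials = 100,
    agent = agent_params(), seed = 55
  )
  d <- build_behavior_design(trials, alpha = 0.257)
  f <- fit_rt_model(d, predictors = character(0))
  intercept <- f$coefficients$estimate[f$coefficients$term == "(Intercept)"]
  kept <- d[!d$is_outlier, ]
  expect_equal(intercept, log(mean(kept$rt_ms)), tolerance = 0.05)
  expect_identical(f$family, "Gamma")
  # excluding lapses drops repeats as well
  f2 <- fit_rt_model(d, predictors = character(0), exclude = "lapses")
  expect_lt(f2$n_obs, f$n_obs + 1)
  # nonpositive RTs are rejected
  d_bad <- d
  d_bad$rt_ms[1] <- -5
  d_bad$is_outlier[1] <- FALSE
  expect_error(fit_rt_model(d_bad), "Nonpositive")
})

test_that("a VS effect on log-RT is recovered in direction", {
  ag <- agent_params(rt_coefs = c(
    intercept = log(500), vs = 0.15, sre = 0,
    rre = 0, position = 0, trialno = 0
  ))
  n_ok <- 0
  for (r in 1:8) {
    trials <- tiny_cohort(
      n_subjects = 2, n_sessions = 2, n_trials = 150,
      agent = ag, seed = 900 + r
    )
    f <- fit_rt_model(build_behavior_design(trials, alpha = 0.257))
    n_ok <- n_ok + (f$coefficients$estimate[f$coefficients$term == "vs"] > 0)
  }
  expect_gte(n_ok, 7)
})
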