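test_that("outcome-probability solver matches the analytic constraints", {
  cases <- list(
    list(mean = 2.0, p2 = 0.1, expect = c(0.45, 0.10, 0.45)),
    list(mean = 2.5, p2 = 0.1, expect = c(0.20, 0.10, 0.70)),
    list(mean = 1.5, p2 = 0.1, expect = c(0.70, 0.10, 0.20)),
    list(mean = 3.0, p2 = 0.0, expect = c(0, 0, 1)),
    list(mean = 2.0, p2 = 1 / 3, expect = c(1 / 3, 1 / 3, 1 / 3))
  )
  for (cs in cases) {
    p <- solve_outcome_probs(cs$mean, cs$p2)
    expect_equal(unname(p), cs$expect, tolerance = 1e-12)
    expect_equal(sum(p), 1)
    expect_equal(sum(p * 1:3), cs$mean)
  }
})

test_that("infeasible mean/p2 combinations are rejected with a message", {
  expect_error(solve_outcome_probs(1.02, 0.1), "infeasible")
  expect_error(solve_outcome_probs(2.95, 0.2), "infeasible")
  expect_error(solve_outcome_probs(0.5, 0.1), "mean_drops")
  expect_error(solve_outcome_probs(2, 1.5), "p2")
})

test_that("count-enforced reward sequences hit exact outcome counts", {
  drops <- generate_reward_sequence(schedule_spec("stable"), seed = 3)
  expect_length(drops, 150)
  expect_identical(sum(drops == 2), 15L)
  expect_equal(mean(drops), 2, tolerance = 2 / 150)

  eq <- generate_reward_sequence(schedule_spec("equiprobable"), seed = 3)
  expect_equal(as.integer(table(factor(eq, 1:3))), c(50L, 50L, 50L))

  ch <- generate_reward_sequence(schedule_spec("changing_up"), seed = 9)
  expect_identical(sum(ch == 2), 15L)
  expect_lt(mean(ch[1:75]), mean(ch[76:150]))
})

test_that("realised per-half means track the specified half means", {
  for (type in c("stable", "changing_up", "changing_down", "equiprobable")) {
    spec <- schedule_spec(type)
    for (seed in 1:5) {
      drops <- generate_reward_sequence(spec, seed = seed)
      n <- length(drops)
      m1 <- mean(drops[seq_len(n / 2)])
      m2 <- mean(drops[(n / 2 + 1):n])
      expect_lte(abs(m1 - spec$half_means[1]), 2 / n + 1e-12)
      expect_lte(abs(m2 - spec$half_means[2]), 2 / n + 1e-12)
    }
  }
})

test_that("iid mode draws from the right per-half distributions", {
  spec <- schedule_spec("changing_up", n_rewarded_trials = 3000)
  drops <- generate_reward_sequence(spec, seed = 4, method = "iid")
  first <- drops[1:1500]
  # 70/10/20 expected in the lean half; allow 4 binomial SDs
  for (k in 1:3) {
    p <- c(0.7, 0.1, 0.2)[k]
    expect_lt(abs(mean(first == k) - p), 4 * sqrt(p * (1 - p) / 1500))
  }
})

test_that("side runs reverse on schedule and offside flips are rare and unbiased", {
  # deterministic construction: fixed run length, no offside
  spec <- schedule_spec("stable",
    n_rewarded_trials = 30,
    run_length_range = c(15, 15), p_offside = 0
  )
  sides <- generate_side_sequence(spec, seed = 2)
  expect_length(unique(sides[1:15]), 1)
  expect_length(unique(sides[16:30]), 1)
  expect_false(sides[1] == sides[16])

  # offside fraction within binomial error at n = 10000
  spec2 <- schedule_spec("stable",
    n_rewarded_trials = 10000,
    run_length_range = c(9999, 10000), p_offside = 0.1
  )
  sides2 <- generate_side_sequence(spec2, seed = 5)
  off <- mean(sides2 != names(which.max(table(sides2))))
  expect_lt(abs(off - 0.1), 4 * sqrt(0.1 * 0.9 / 10000))

  # empirical mean run length ~ 15 under the default 11-19 range
  spec3 <- schedule_spec("stable", n_rewarded_trials = 6000, p_offside = 0)
  sides3 <- generate_side_sequence(spec3, seed = 6)
  runs <- rle(sides3)$lengths
  runs <- runs[-length(runs)] # last run is truncated
  expect_gt(mean(runs), 14)
  expect_lt(mean(runs), 16)
  expect_true(all(runs >= 11 & runs <= 19))
})

test_that("sessions are reproducible, ordered in time, and independent across streams", {
  spec <- schedule_spec("changing_up")
  s1 <- generate_session(spec, seed = 42)
  s2 <- generate_session(spec, seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(diff(s1$t_decision) > 0))
  expect_true(all(s1$t_outcome > s1$t_decision))
  expect_lt(mean(s1$drops[s1$half == "first"]), mean(s1$drops[s1$half == "second"]))

  # drops and sides independent: pooled chi-squared over 200 seeded sessions
  tab <- matrix(0, 3, 2, dimnames = list(1:3, c("left", "right")))
  for (seed in 1:200) {
    s <- generate_session(schedule_spec("stable"), seed = seed)
    tab <- tab + table(factor(s$drops, 1:3), factor(s$side, c("left", "right")))
  }
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})

test_that("session TSV round-trips", {
  s <- generate_session(schedule_spec("stable", n_rewarded_trials = 12), seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_session_tsv(s, path)
  back <- read_session_tsv(path)
  expect_equal(back$drops, s$drops)
  expect_equal(back$t_outcome, s$t_outcome, tolerance = 1e-8)
})
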