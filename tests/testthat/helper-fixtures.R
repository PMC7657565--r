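# Shared helpers: tiny deterministic fixtures and independent oracles.

# Independent Rescorla-Wagner recursion (oracle for compute_sre and the sre
# design column); deliberately written as a plain loop.
oracle_rw <- function(drops, alpha, v0) {
  v <- v0
  out <- numeric(length(drops) + 1)
  out[1] <- v0
  for (t in seq_along(drops)) {
    v <- v + alpha * (drops[t] - v)
    out[t + 1] <- v
  }
  out
}

# Geometric lag weights written independently of rw_lag_weights()
oracle_lag_weights <- function(alpha, k = 5) {
  vapply(seq_len(k), function(j) alpha * (1 - alpha)^(j - 1), 0)
}

# Dense-grid brute-force minimiser of the truncated-RW norm (oracle for
# fit_truncated_rw's grid + refinement path).
oracle_rw_gridfit <- function(b, n_grid = 20001) {
  grid <- seq(0, 1, length.out = n_grid)
  best <- c(alpha = NA, res = Inf)
  for (a in grid) {
    w <- a * (1 - a)^(0:4)
    ss <- sum(w^2)
    r <- if (ss == 0) sqrt(sum(b^2)) else sqrt(sum((b - sum(b * w) / ss * w)^2))
    if (r < best["res"]) best <- c(alpha = a, res = r)
  }
  best
}

# Small simulated cohort: returns the bound trial table
tiny_cohort <- function(n_subjects = 2, n_sessions = 2, n_trials = 60,
                        agent = agent_params(), seed = 1,
                        type = "stable") {
  recs <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_sessions)) {
      s <- generate_session(
        schedule_spec(type, n_rewarded_trials = n_trials),
        seed = derive_seed(seed, i, j, "sched")
      )
      tr <- simulate_behavior(s, agent, seed = derive_seed(seed, i, j, "beh"))
      tr$subject <- sprintf("m%02d", i)
      tr$session <- sprintf("m%02d_s%02d", i, j)
      recs[[length(recs) + 1]] <- tr
    }
  }
  dplyr::bind_rows(recs)
}
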