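#' Trial timing parameters
#'
#' Event timing of one trial: a blank screen precedes stimulus onset
#' (uniform 2--4 s, mean 3 s), reward is delivered 200 ms after the correct
#' response, juice delivery lasts 1.5 s, and trials are separated by an
#' intertrial interval of 2--4 s (mean 3 s).
#'
#' @param pre_stim_blank Length-2 numeric, uniform range (s) of the blank
#'   before stimulus onset.
#' @param reward_delay Delay (s) between response and reward onset.
#' @param juice_duration Duration (s) of juice delivery.
#' @param iti Length-2 numeric, uniform range (s) of the intertrial interval.
#' @param rt_nominal Nominal response time (s) used to place outcome onsets
#'   when a session is generated without a behavioural agent.
#' @return A list of class `rws_timing`.
#' @export
timing_spec <- function(pre_stim_blank = c(2, 4), reward_delay = 0.2,
                        juice_duration = 1.5, iti = c(2, 4),
                        rt_nominal = 0.5) {
  stopifnot(
    length(pre_stim_blank) == 2, all(pre_stim_blank >= 0),
    diff(pre_stim_blank) >= 0,
    reward_delay >= 0, juice_duration >= 0,
    length(iti) == 2, all(iti >= 0), diff(iti) >= 0,
    rt_nominal >= 0
  )
  structure(
    list(
      pre_stim_blank = as.numeric(pre_stim_blank),
      reward_delay = reward_delay,
      juice_duration = juice_duration,
      iti = as.numeric(iti),
      rt_nominal = rt_nominal
    ),
    class = "rws_timing"
  )
}

#' Specify a reward-schedule session
#'
#' Parameterises one session of the reward task. Sessions deliver 1, 2 or 3
#' drops of juice per rewarded trial. Four session types are supported:
#'
#' * `stable`: mean reward 2 drops throughout; 2 drops (the rare-reward
#'   event, RRE) delivered on 10% of trials, 1 and 3 drops on 45% each.
#' * `changing_up` / `changing_down`: mean reward 1.5 then 2.5 drops (or the
#'   reverse) in the two halves, with 2 drops still on 10% of trials.
#' * `equiprobable`: each outcome with probability 1/3 (control; RRE is no
#'   longer rare).
#'
#' Stimuli stay on one side of the screen for runs of 11--19 trials
#' (mean 15) before reversing; within a run each stimulus is independently
#' displaced to the opposite side with probability `p_offside` (the
#' visuospatial surprise, VS, events).
#'
#' @param session_type One of `"stable"`, `"changing_up"`, `"changing_down"`,
#'   `"equiprobable"`.
#' @param n_rewarded_trials Number of rewarded (correct) trials (> 5).
#' @param p_rre Probability of the 2-drop outcome. Defaults to 0.1
#'   (1/3 for equiprobable sessions).
#' @param half_means Length-2 numeric, mean drops in the first and second
#'   half. Defaults per session type.
#' @param run_length_range Inclusive integer range of same-side run lengths.
#' @param p_offside Probability that a trial within a run appears on the
#'   opposite side.
#' @param timing A [timing_spec()].
#' @return A list of class `rws_schedule_spec`.
#' @examples
#' spec <- schedule_spec("stable")
#' spec$half_means
#' @export
schedule_spec <- function(session_type = c("stable", "changing_up",
                                           "changing_down", "equiprobable"),
                          n_rewarded_trials = 150,
                          p_rre = NULL,
                          half_means = NULL,
                          run_length_range = c(11L, 19L),
                          p_offside = 0.1,
                          timing = timing_spec()) {
  session_type <- match.arg(session_type)
  if (is.null(p_rre)) {
    p_rre <- if (session_type == "equiprobable") 1 / 3 else 0.1
  }
  if (is.null(half_means)) {
    half_means <- switch(session_type,
      stable = c(2, 2),
      changing_up = c(1.5, 2.5),
      changing_down = c(2.5, 1.5),
      equiprobable = c(2, 2)
    )
  }
  if (!(is.numeric(n_rewarded_trials) && n_rewarded_trials > 5)) {
    abort("`n_rewarded_trials` must be > 5.")
  }
  if (p_rre < 0 || p_rre > 1) abort("`p_rre` must be in [0, 1].")
  if (length(half_means) != 2 || any(half_means < 1) || any(half_means > 3)) {
    abort("`half_means` must be two values in [1, 3].")
  }
  stopifnot(
    length(run_length_range) == 2,
    run_length_range[1] <= run_length_range[2],
    run_length_range[1] >= 1,
    p_offside >= 0, p_offside <= 1,
    inherits(timing, "rws_timing")
  )
  # validate feasibility of each half's outcome distribution up front
  for (m in half_means) solve_outcome_probs(m, p_rre)
  structure(
    list(
      session_type = session_type,
      n_rewarded_trials = as.integer(n_rewarded_trials),
      p_rre = p_rre,
      half_means = as.numeric(half_means),
      run_length_range = as.integer(run_length_range),
      p_offside = p_offside,
      timing = timing
    ),
    class = "rws_schedule_spec"
  )
}

#' @export
print.rws_schedule_spec <- function(x, ...) {
  cat(
    "<schedule_spec>", x$session_type, "\n",
    " trials:", x$n_rewarded_trials,
    " P(2 drops):", format(x$p_rre, digits = 4),
    " half means:", paste(x$half_means, collapse = "/"), "\n",
    " runs:", paste(x$run_length_range, collapse = "-"),
    " P(offside):", x$p_offside, "\n"
  )
  invisible(x)
}

#' Solve the three-outcome distribution from its mean and the 2-drop rate
#'
#' Outcomes are 1, 2 or 3 drops of juice. Given the target mean and the
#' probability `p2` of the 2-drop outcome, the remaining two probabilities
#' are determined by the constraints `p1 + p2 + p3 = 1` and
#' `p1 + 2 p2 + 3 p3 = mean_drops`, giving
#' `p3 = (mean_drops - 1 - p2) / 2` and `p1 = 1 - p2 - p3`.
#'
#' @param mean_drops Target mean reward in drops, in `[1, 3]`.
#' @param p2 Probability of the 2-drop outcome.
#' @return Named numeric vector `c(p1, p2, p3)`.
#' @examples
#' solve_outcome_probs(2.0, 0.1) # stable: 45/10/45
#' solve_outcome_probs(2.5, 0.1) # rich half: 20/10/70
#' @export
solve_outcome_probs <- function(mean_drops, p2) {
  stopifnot(length(mean_drops) == 1, length(p2) == 1)
  if (p2 < 0 || p2 > 1) abort("`p2` must be in [0, 1].")
  if (mean_drops < 1 || mean_drops > 3) abort("`mean_drops` must be in [1, 3].")
  p3 <- (mean_drops - 1 - p2) / 2
  p1 <- 1 - p2 - p3
  if (p3 < -1e-12 || p1 < -1e-12) {
    abort(sprintf(
      "Mean of %.3f drops is infeasible with P(2 drops) = %.3f: it requires P(1) = %.3f and P(3) = %.3f.",
      mean_drops, p2, p1, p3
    ))
  }
  c(p1 = max(p1, 0), p2 = p2, p3 = max(p3, 0))
}

# Largest-remainder rounding of non-negative targets to integers summing to
# `total` (default: the rounded sum). Ties go to the lower index.
largest_remainder <- function(targets, total = round(sum(targets))) {
  fl <- floor(targets + 1e-9)
  rem <- targets - fl
  k <- as.integer(total - sum(fl))
  if (k > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(k)]
    fl[idx] <- fl[idx] + 1
  } else if (k < 0) {
    idx <- order(rem, decreasing = FALSE)[seq_len(-k)]
    fl[idx] <- fl[idx] - 1
  }
  as.integer(fl)
}

# Integer outcome counts for one half: n2 is fixed by the session-level
# 2-drop allocation; n3 is chosen so the realised half mean is as close as
# possible to `mean_drops`. Exact half-unit ties take `tie_up` (resolved by
# the caller so the two halves round in opposite directions and the session
# mean stays exact).
half_outcome_counts <- function(h, n2, mean_drops, tie_up = NA) {
  n3_ideal <- (mean_drops * h - h - n2) / 2
  lo <- floor(n3_ideal + 1e-9)
  frac <- n3_ideal - lo
  n3 <- if (abs(frac - 0.5) < 1e-9) {
    if (is.na(tie_up)) tie_up <- stats::rbinom(1, 1, 0.5) == 1
    lo + as.integer(tie_up)
  } else {
    lo + as.integer(frac > 0.5)
  }
  n3 <- max(0L, min(as.integer(n3), h - n2))
  n1 <- h - n2 - n3
  c(n1 = n1, n2 = as.integer(n2), n3 = as.integer(n3))
}

# TRUE where the half's 1-vs-3 allocation lands on an exact half-unit tie
half_has_tie <- function(h, n2, mean_drops) {
  n3_ideal <- (mean_drops * h - h - n2) / 2
  abs(n3_ideal - floor(n3_ideal + 1e-9) - 0.5) < 1e-9
}

#' Generate the reward (drops) sequence of a session
#'
#' By default outcome counts are enforced exactly (`method = "count"`): the
#' session-level number of 2-drop trials is `p_rre * n` (exact whenever that
#' is an integer, e.g. 15 of 150 at `p_rre = 0.1`), split across halves, and
#' 1- vs 3-drop counts within each half are the largest-remainder rounding
#' that matches the half mean; the order within each half is a seeded uniform
#' shuffle. `method = "iid"` instead draws every trial independently from the
#' half's outcome distribution.
#'
#' @param spec A [schedule_spec()].
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param method `"count"` (exact proportions, default) or `"iid"`.
#' @return Integer vector of drops (1, 2 or 3), length `n_rewarded_trials`.
#' @examples
#' drops <- generate_reward_sequence(schedule_spec("stable"), seed = 1)
#' table(drops)
#' @export
generate_reward_sequence <- function(spec, seed = NULL,
                                     method = c("count", "iid")) {
  stopifnot(inherits(spec, "rws_schedule_spec"))
  method <- match.arg(method)
  n <- spec$n_rewarded_trials
  h1 <- n %/% 2L
  h2 <- n - h1
  with_seed_(seed, {
    if (method == "iid") {
      p_first <- solve_outcome_probs(spec$half_means[1], spec$p_rre)
      p_second <- solve_outcome_probs(spec$half_means[2], spec$p_rre)
      drops <- c(
        sample(1:3, h1, replace = TRUE, prob = p_first),
        sample(1:3, h2, replace = TRUE, prob = p_second)
      )
      return(as.integer(drops))
    }
    # session-level 2-drop count first (exact when p_rre * n is integral),
    # then split across halves by largest remainder (0.5/0.5 ties seeded)
    targets2 <- spec$p_rre * c(h1, h2)
    n2_total <- round(spec$p_rre * n)
    rem <- targets2 - floor(targets2 + 1e-9)
    if (abs(rem[1] - rem[2]) < 1e-9 &&
      n2_total - sum(floor(targets2 + 1e-9)) == 1) {
      extra_to_first <- stats::rbinom(1, 1, 0.5) == 1
      n2_halves <- floor(targets2 + 1e-9) + if (extra_to_first) c(1, 0) else c(0, 1)
    } else {
      n2_halves <- largest_remainder(targets2, total = n2_total)
    }
    # opposite tie directions keep the session mean exact when both halves
    # land on half-unit 1-vs-3 splits
    ties <- c(
      half_has_tie(h1, n2_halves[1], spec$half_means[1]),
      half_has_tie(h2, n2_halves[2], spec$half_means[2])
    )
    tie_up <- c(NA, NA)
    if (any(ties)) {
      first_up <- stats::rbinom(1, 1, 0.5) == 1
      tie_up <- if (all(ties)) c(first_up, !first_up) else rep(first_up, 2)
    }
    halves <- list(c(h1, n2_halves[1], 1), c(h2, n2_halves[2], 2))
    drops <- unlist(lapply(halves, function(hh) {
      cnt <- half_outcome_counts(
        hh[1], hh[2], spec$half_means[hh[3]],
        tie_up = tie_up[hh[3]]
      )
      pool <- rep(1:3, times = cnt)
      pool[sample.int(length(pool))]
    }))
    as.integer(drops)
  })
}

#' Generate the stimulus-side sequence of a session
#'
#' Sides are organised in runs whose lengths are drawn uniformly from
#' `run_length_range` (inclusive); after each run the side reverses and a new
#' length is drawn. Within a run, each trial is independently displaced to
#' the opposite side with probability `p_offside` (a VS event); offside
#' trials do not reset the run. The side of the first run is random.
#'
#' @inheritParams generate_reward_sequence
#' @return Character vector (`"left"`/`"right"`), length `n_rewarded_trials`.
#' @export
generate_side_sequence <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "rws_schedule_spec"))
  n <- spec$n_rewarded_trials
  rng <- spec$run_length_range
  with_seed_(seed, {
    base <- character(0)
    side <- sample(c("left", "right"), 1)
    while (length(base) < n) {
      len <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
      base <- c(base, rep(side, len))
      side <- if (side == "left") "right" else "left"
    }
    base <- base[seq_len(n)]
    flip <- runif(n) < spec$p_offside
    out <- ifelse(flip, ifelse(base == "left", "right", "left"), base)
    out
  })
}

#' Generate a full session
#'
#' Composes the reward and side generators (independent substreams derived
#' from `seed`, so the two sequences are independent by construction) and
#' assigns decision and outcome onset times from the timing parameters:
#' blank (2--4 s) -> stimulus onset (decision) -> nominal response time ->
#' 200 ms delay -> outcome onset -> 1.5 s juice -> intertrial interval
#' (2--4 s).
#'
#' @inheritParams generate_reward_sequence
#' @return A tibble of class `rws_session` with one row per rewarded trial:
#'   `trial`, `drops`, `side`, `half`, `t_decision`, `t_outcome` (seconds
#'   from session start). The generating spec is kept in attribute `"spec"`.
#' @examples
#' s <- generate_session(schedule_spec("stable"), seed = 7)
#' mean(s$drops == 2)
#' @export
generate_session <- function(spec, seed = NULL,
                             method = c("count", "iid")) {
  stopifnot(inherits(spec, "rws_schedule_spec"))
  method <- match.arg(method)
  n <- spec$n_rewarded_trials
  seeds <- if (is.null(seed)) {
    list(rewards = NULL, sides = NULL, timing = NULL)
  } else {
    list(
      rewards = derive_seed(seed, "rewards"),
      sides = derive_seed(seed, "sides"),
      timing = derive_seed(seed, "timing")
    )
  }
  drops <- generate_reward_sequence(spec, seeds$rewards, method = method)
  sides <- generate_side_sequence(spec, seeds$sides)
  tm <- spec$timing
  timing <- with_seed_(seeds$timing, {
    blanks <- runif(n, tm$pre_stim_blank[1], tm$pre_stim_blank[2])
    itis <- runif(n, tm$iti[1], tm$iti[2])
    list(blanks = blanks, itis = itis)
  })
  t_decision <- numeric(n)
  t_outcome <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t_decision[i] <- t + timing$blanks[i]
    t_outcome[i] <- t_decision[i] + tm$rt_nominal + tm$reward_delay
    t <- t_outcome[i] + tm$juice_duration + timing$itis[i]
  }
  out <- tibble(
    trial = seq_len(n),
    drops = drops,
    side = sides,
    half = ifelse(seq_len(n) <= n %/% 2L, "first", "second"),
    t_decision = t_decision,
    t_outcome = t_outcome
  )
  attr(out, "spec") <- spec
  class(out) <- c("rws_session", class(out))
  out
}

#' Write / read a session as TSV
#'
#' @param session An `rws_session` tibble.
#' @param path File path.
#' @return `write_session_tsv()` returns `path` invisibly;
#'   `read_session_tsv()` returns a tibble.
#' @export
write_session_tsv <- function(session, path) {
  utils::write.table(as.data.frame(session), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
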