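#' Generative behavioural agent parameters
#'
#' Parameters of the agent that produces performance lapses (errors and
#' outlier reaction times) and gamma-distributed RTs. Lapse probability is a
#' logistic function of z-scored visuospatial surprise (VS), scalar reward
#' expectation (sRE, the Rescorla-Wagner value estimate), previous-trial
#' rare-reward event (RRE), stimulus position and trial number; log mean RT
#' is a linear function of the same predictors.
#'
#' Defaults: `alpha = 0.257` with `v0 = 2` drops (animals trained on a
#' long-run mean of 2 drops carry that prior into each session); a lapse-model
#' intercept of `qlogis(0.11)` giving a baseline lapse rate of ~11%, mid-range
#' of typical observed per-animal rates (~7-16%); VS and time-on-task
#' increase lapses, higher reward expectation reduces them, RRE has no
#' behavioural effect; VS slows RTs; RT shape 20 (CV ~ 22%) around a 500 ms
#' baseline.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param v0 Initial value estimate (drops).
#' @param lapse_coefs Named numeric: `intercept`, `vs`, `sre`, `rre`,
#'   `position`, `trialno` (logit scale, z-scored predictors).
#' @param rt_coefs Same names, log-RT (ms) scale.
#' @param rt_shape Gamma shape of the RT distribution (> 0).
#' @param p_error Probability that a realised lapse is an error response
#'   (otherwise it is an outlier RT, uniform 4000--6000 ms).
#' @return A list of class `rws_agent`.
#' @export
agent_params <- function(alpha = 0.257,
                         v0 = 2,
                         lapse_coefs = c(
                           intercept = qlogis(0.11), vs = 0.4, sre = -0.3,
                           rre = 0, position = 0, trialno = 0.15
                         ),
                         rt_coefs = c(
                           intercept = log(500), vs = 0.06, sre = 0,
                           rre = 0, position = 0, trialno = 0.02
                         ),
                         rt_shape = 20,
                         p_error = 0.5) {
  nm <- c("intercept", "vs", "sre", "rre", "position", "trialno")
  stopifnot(
    alpha >= 0, alpha <= 1, rt_shape > 0,
    p_error >= 0, p_error <= 1,
    all(nm %in% names(lapse_coefs)), all(nm %in% names(rt_coefs))
  )
  structure(
    list(
      alpha = alpha, v0 = v0,
      lapse_coefs = lapse_coefs[nm], rt_coefs = rt_coefs[nm],
      rt_shape = rt_shape, p_error = p_error
    ),
    class = "rws_agent"
  )
}

#' Scalar reward expectation trace (Rescorla-Wagner)
#'
#' Runs the Rescorla-Wagner update `V[t+1] = V[t] + alpha * (r[t] - V[t])`
#' over a reward sequence. Element `t` of the returned trace is the
#' expectation held going into trial `t` (the pre-outcome value); the final
#' element is the value after the last outcome, so the trace has length
#' `length(drops) + 1`.
#'
#' @param drops Numeric reward sequence (drops per rewarded trial).
#' @param alpha Learning rate in `[0, 1]`.
#' @param v0 Initial value estimate.
#' @return Numeric vector of length `length(drops) + 1`.
#' @examples
#' compute_sre(c(1, 3), alpha = 0.257, v0 = 2)
#' @export
compute_sre <- function(drops, alpha, v0 = 2) {
  stopifnot(alpha >= 0, alpha <= 1)
  n <- length(drops)
  v <- numeric(n + 1)
  v[1] <- v0
  if (n == 0) {
    return(v)
  }
  for (t in seq_len(n)) {
    v[t + 1] <- v[t] + alpha * (drops[t] - v[t])
  }
  v
}

#' Simulate the behaviour of an agent on a session
#'
#' Walks through the rewarded trials of a session. On each attempt the agent
#' lapses with probability `plogis(intercept + b . z)`, where `z` are the
#' session-z-scored predictors (VS, sRE, previous-trial RRE, position, trial
#' number). A lapse is realised as an error response (probability
#' `p_error`), which repeats the trial -- the repeated attempt has no VS and
#' no RRE regressor by the task's zeroing rule -- or as an outlier RT
#' (uniform 4000--6000 ms) on an otherwise correct response. Non-lapse RTs
#' are gamma with log-link mean. Reward is delivered (and the value estimate
#' updated) only on the correct attempt of each trial.
#'
#' @param session An `rws_session` tibble from [generate_session()].
#' @param agent An [agent_params()] object.
#' @param seed Integer seed (`NULL` for the current stream).
#' @param max_attempts Safety cap on repeats of one trial.
#' @return A tibble of class `rws_trials`, one row per attempt: `trial`,
#'   `attempt`, `side`, `responded_side`, `is_error`, `rt_ms`, `is_outlier`,
#'   `drops` (NA on error attempts), `vs_raw`, `vs_zeroed`, `rre_prev`,
#'   `sre`.
#' @export
simulate_behavior <- function(session, agent, seed = NULL, max_attempts = 10) {
  stopifnot(inherits(agent, "rws_agent"))
  n <- nrow(session)
  drops <- session$drops
  side <- session$side
  # Predictors that do not depend on lapses are known up front, so the
  # generative model can use the same per-session z-scoring as the fit.
  vs_raw <- c(0L, as.integer(side[-1] != side[-n]))
  rre_prev <- c(0L, as.integer(drops[-n] == 2))
  sre <- compute_sre(drops, agent$alpha, agent$v0)[seq_len(n)]
  pos <- as.integer(side == "right")
  z <- list(
    vs = zscore(vs_raw), sre = zscore(sre), rre = zscore(rre_prev),
    position = zscore(pos), trialno = zscore(seq_len(n))
  )
  # z-value corresponding to a raw 0 (used when a predictor is zeroed out on
  # repeated attempts)
  z0 <- function(raw, zs) if (sd(raw) == 0) 0 else -mean(raw) / sd(raw)
  z0_vs <- z0(vs_raw, z$vs)
  z0_rre <- z0(rre_prev, z$rre)
  b <- agent$lapse_coefs
  br <- agent$rt_coefs
  with_seed_(seed, {
    cap <- 2L * n + 16L
    c_trial <- integer(cap)
    c_attempt <- integer(cap)
    c_side <- character(cap)
    c_resp <- character(cap)
    c_err <- logical(cap)
    c_rt <- numeric(cap)
    c_out <- logical(cap)
    c_drops <- rep(NA_integer_, cap)
    c_vsraw <- integer(cap)
    c_rre <- integer(cap)
    c_sre <- numeric(cap)
    i <- 0L
    intercept <- b[["intercept"]]
    for (t in seq_len(n)) {
      attempt <- 1L
      repeat {
        repeated <- attempt > 1L
        zv <- if (repeated) z0_vs else z$vs[t]
        zr <- if (repeated) z0_rre else z$rre[t]
        lp <- intercept + b[["vs"]] * zv + b[["sre"]] * z$sre[t] +
          b[["rre"]] * zr + b[["position"]] * z$position[t] +
          b[["trialno"]] * z$trialno[t]
        lapse <- runif(1) < plogis(lp)
        is_error <- lapse && runif(1) < agent$p_error &&
          attempt < max_attempts
        is_outlier <- lapse && !is_error
        mu <- exp(br[["intercept"]] + br[["vs"]] * zv +
          br[["sre"]] * z$sre[t] + br[["rre"]] * zr +
          br[["position"]] * z$position[t] + br[["trialno"]] * z$trialno[t])
        rt <- if (is_outlier) {
          runif(1, 4000, 6000)
        } else {
          rgamma(1, shape = agent$rt_shape, scale = mu / agent$rt_shape)
        }
        i <- i + 1L
        if (i > cap) {
          grow <- function(x) c(x, x) # double capacity
          cap <- 2L * cap
          c_trial <- grow(c_trial); c_attempt <- grow(c_attempt)
          c_side <- grow(c_side); c_resp <- grow(c_resp)
          c_err <- grow(c_err); c_rt <- grow(c_rt); c_out <- grow(c_out)
          c_drops <- grow(c_drops); c_vsraw <- grow(c_vsraw)
          c_rre <- grow(c_rre); c_sre <- grow(c_sre)
        }
        c_trial[i] <- t
        c_attempt[i] <- attempt
        c_side[i] <- side[t]
        c_resp[i] <- if (is_error) {
          if (side[t] == "left") "right" else "left"
        } else {
          side[t]
        }
        c_err[i] <- is_error
        c_rt[i] <- rt
        c_out[i] <- is_outlier
        c_drops[i] <- if (is_error) NA_integer_ else drops[t]
        c_vsraw[i] <- if (repeated) 0L else vs_raw[t]
        c_rre[i] <- if (repeated) 0L else rre_prev[t]
        c_sre[i] <- sre[t]
        if (!is_error) break
        attempt <- attempt + 1L
      }
    }
    idx <- seq_len(i)
    out <- tibble(
      trial = c_trial[idx], attempt = c_attempt[idx],
      side = c_side[idx], responded_side = c_resp[idx],
      is_error = c_err[idx], rt_ms = c_rt[idx], is_outlier = c_out[idx],
      drops = c_drops[idx],
      vs_raw = c_vsraw[idx], vs_zeroed = c_vsraw[idx],
      rre_prev = c_rre[idx], sre = c_sre[idx]
    )
    class(out) <- c("rws_trials", class(out))
    out
  })
}

#' Flag outlier reaction times
#'
#' A trial is an outlier if its RT exceeds 4000 ms (task disengagement) or
#' falls below 50 ms (impulsive responding). Additionally, among the trials
#' not caught by the absolute thresholds, RTs more than 2.5 standard
#' deviations from that subset's mean are flagged (zero-variance input
#' applies the absolute thresholds only).
#'
#' @param rts Numeric vector of RTs in milliseconds.
#' @param abs_high,abs_low Absolute thresholds (ms).
#' @param n_sd Relative threshold in standard deviations.
#' @return Logical vector of outlier flags.
#' @examples
#' label_outliers(c(100, 200, 5000))
#' @export
label_outliers <- function(rts, abs_high = 4000, abs_low = 50, n_sd = 2.5) {
  if (length(rts) == 0) abort("`rts` must be nonempty.")
  flag <- rts > abs_high | rts < abs_low
  keep <- !flag & !is.na(rts)
  if (sum(keep) >= 2) {
    m <- mean(rts[keep])
    s <- sd(rts[keep])
    if (is.finite(s) && s > 0) {
      flag <- flag | (abs(rts - m) > n_sd * s)
    }
  }
  flag
}
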