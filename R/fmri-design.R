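#' Gamma haemodynamic response function
#'
#' A single-gamma HRF parameterised by its mean lag and standard deviation
#' (macaque haemodynamics are faster than human; the defaults give a kernel
#' with mean 4.5 s, SD 2 s, and mode `(shape - 1) * scale = 3.61` s).
#' Moment matching gives `shape = (mean/sd)^2` and `scale = sd^2/mean`;
#' `shape` must exceed 1 so an interior mode exists. The sampled kernel is
#' normalised to unit sum.
#'
#' @param mean_lag Mean of the gamma kernel (s).
#' @param sd Standard deviation of the kernel (s).
#' @param dt Sampling step (s).
#' @param duration Kernel support (s).
#' @return For `hrf_spec()`, a list of class `rws_hrf`; for `hrf_kernel()`,
#'   a numeric vector (unit sum) with attributes `"time"` and `"dt"`.
#' @examples
#' k <- hrf_kernel(hrf_spec())
#' attr(k, "time")[which.max(k)] # ~3.6 s
#' @export
hrf_spec <- function(mean_lag = 4.5, sd = 2, dt = 0.1, duration = 30) {
  shape <- (mean_lag / sd)^2
  if (shape <= 1) {
    abort("Gamma shape (mean_lag/sd)^2 must exceed 1 so the kernel has a mode.")
  }
  stopifnot(dt > 0, duration > dt)
  structure(
    list(
      mean_lag = mean_lag, sd = sd, dt = dt, duration = duration,
      shape = shape, scale = sd^2 / mean_lag
    ),
    class = "rws_hrf"
  )
}

#' @rdname hrf_spec
#' @param spec An `rws_hrf` object.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "rws_hrf"))
  tt <- seq(0, spec$duration, by = spec$dt)
  k <- dgamma(tt, shape = spec$shape, scale = spec$scale)
  k <- k / sum(k)
  attr(k, "time") <- tt
  attr(k, "dt") <- spec$dt
  k
}

# Causal FFT convolution of every column of `x` with kernel `k` (linear, not
# circular: zero-padded to length n + length(k)).
fft_convolve_cols <- function(x, k) {
  n <- nrow(x)
  m <- stats::nextn(n + length(k), 2)
  kf <- stats::fft(c(k, numeric(m - length(k))))
  xp <- rbind(x, matrix(0, m - n, ncol(x)))
  xf <- stats::mvfft(xp)
  out <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / m
  out <- out[seq_len(n), , drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

# Regressor names built for every session (13 named; a config hook allows
# extra nuisance columns).
fmri_regressor_names <- function(n_lags = 5) {
  c(
    "VS_left", "VS_right", "RRE_decision", "const_decision", "hand_movement",
    "reward_current", paste0("reward_lag", seq_len(n_lags)),
    "RRE_outcome", "const_outcome"
  )
}

#' Build the event-related fMRI design matrix for one session
#'
#' Events are modelled as impulses on a fine time grid, convolved with the
#' gamma HRF, sampled at the TR, and z-scored. Decision-phase regressors
#' (at stimulus onset): `VS_left` / `VS_right` (visuospatial surprise split
#' by stimulus side, zeroed after errors when a trial table is supplied),
#' `RRE_decision` (the previous trial's reward was 2 drops), a decision
#' constant, and `hand_movement` at the response. Outcome-phase regressors
#' (at reward onset): `reward_current` with amplitude equal to the delivered
#' drops, `reward_lag1` ... `reward_lag5` with the amplitudes of the 5
#' previous rewards (all placed at the current outcome onset),
#' `RRE_outcome` (current reward is 2 drops), and an outcome constant.
#' Optional boxcar mode spreads outcome events over the juice duration.
#'
#' @param session An `rws_session` tibble.
#' @param trials Optional `rws_trials` table from [simulate_behavior()];
#'   when given, VS and decision-phase RRE are zeroed after errors and the
#'   response (hand movement) time uses the realised RTs.
#' @param tr Repetition time (s), default 2.28.
#' @param n_volumes Number of volumes; default covers the last event plus
#'   20 s.
#' @param hrf An [hrf_spec()].
#' @param n_lags Number of lagged-reward regressors.
#' @param boxcar If TRUE, outcome events last the juice duration (1.5 s)
#'   instead of being impulses.
#' @param extra_nuisance Optional named list of event-time vectors; each
#'   becomes one extra convolved nuisance regressor.
#' @return An object of class `rws_fmri_design`: list with `design` (tibble
#'   `volume`, `time`, one column per regressor), `tr`, `n_volumes`,
#'   `regressors`, `constant_cols` (all-zero columns, e.g. RRE in a session
#'   with no 2-drop outcome), `truncated_events`.
#' @export
build_fmri_design <- function(session, trials = NULL, tr = 2.28,
                              n_volumes = NULL, hrf = hrf_spec(),
                              n_lags = 5, boxcar = FALSE,
                              extra_nuisance = NULL) {
  n <- nrow(session)
  dt <- hrf$dt
  spec <- attr(session, "spec")
  juice <- if (!is.null(spec)) spec$timing$juice_duration else 1.5
  reward_delay <- if (!is.null(spec)) spec$timing$reward_delay else 0.2
  drops <- session$drops
  # VS flags: raw side changes, zeroed after errors when trials are known
  vs <- c(0L, as.integer(session$side[-1] != session$side[-n]))
  rre_dec <- c(0L, as.integer(drops[-n] == 2))
  t_response <- session$t_outcome - reward_delay
  if (!is.null(trials)) {
    first <- trials[trials$attempt == 1, ]
    first <- first[order(first$trial), ]
    if (nrow(first) == n) {
      vs <- as.integer(first$vs_zeroed)
      rre_dec <- as.integer(first$rre_prev)
    }
    correct <- trials[!trials$is_error, ]
    correct <- correct[order(correct$trial), ]
    if (nrow(correct) == n) {
      t_response <- session$t_decision + correct$rt_ms / 1000
      session <- session %>%
        mutate(t_outcome = t_response + reward_delay)
    }
  }
  t_end_event <- max(session$t_outcome) + if (boxcar) juice else 0
  n_volumes <- if (is.null(n_volumes)) {
    as.integer(ceiling((t_end_event + 20) / tr))
  } else {
    as.integer(n_volumes)
  }
  scan_end <- n_volumes * tr
  truncated <- sum(session$t_outcome > scan_end)
  if (truncated > 0) {
    warn(sprintf("%d event(s) fall after the scan end and are truncated.", truncated))
  }
  lagmat <- sapply(seq_len(n_lags), function(k) {
    c(rep(0, k), drops)[seq_len(n)]
  })
  events <- list(
    VS_left = list(t = session$t_decision, a = vs * (session$side == "left")),
    VS_right = list(t = session$t_decision, a = vs * (session$side == "right")),
    RRE_decision = list(t = session$t_decision, a = rre_dec),
    const_decision = list(t = session$t_decision, a = rep(1, n)),
    hand_movement = list(t = t_response, a = rep(1, n)),
    reward_current = list(t = session$t_outcome, a = drops, box = TRUE),
    RRE_outcome = list(t = session$t_outcome, a = as.integer(drops == 2), box = TRUE),
    const_outcome = list(t = session$t_outcome, a = rep(1, n), box = TRUE)
  )
  for (k in seq_len(n_lags)) {
    events[[paste0("reward_lag", k)]] <-
      list(t = session$t_outcome, a = lagmat[, k], box = TRUE)
  }
  if (!is.null(extra_nuisance)) {
    for (nm in names(extra_nuisance)) {
      events[[nm]] <- list(t = extra_nuisance[[nm]], a = rep(1, length(extra_nuisance[[nm]])))
    }
  }
  reg_names <- c(fmri_regressor_names(n_lags), names(extra_nuisance))
  kern <- hrf_kernel(hrf)
  n_fine <- ceiling(scan_end / dt) + 1L
  t_vol <- (seq_len(n_volumes) - 1) * tr
  vol_idx <- pmin(round(t_vol / dt) + 1L, n_fine)
  sticks <- matrix(0, n_fine, length(reg_names),
    dimnames = list(NULL, reg_names)
  )
  for (nm in reg_names) {
    ev <- events[[nm]]
    keep <- ev$t >= 0 & ev$t <= scan_end & ev$a != 0
    if (!any(keep)) next
    idx <- round(ev$t[keep] / dt) + 1L
    if (boxcar && isTRUE(ev$box)) {
      width <- max(1L, round(juice / dt))
      for (j in seq_along(idx)) {
        span <- idx[j]:min(idx[j] + width - 1L, n_fine)
        sticks[span, nm] <- sticks[span, nm] + ev$a[keep][j]
      }
    } else {
      for (j in seq_along(idx)) {
        sticks[idx[j], nm] <- sticks[idx[j], nm] + ev$a[keep][j]
      }
    }
  }
  conv <- fft_convolve_cols(sticks, kern)
  cols <- lapply(reg_names, function(nm) conv[vol_idx, nm])
  names(cols) <- reg_names
  constant_cols <- reg_names[vapply(cols, function(x) sd(x) == 0, TRUE)]
  cols <- lapply(cols, zscore)
  design <- as_tibble(c(
    list(volume = seq_len(n_volumes), time = t_vol),
    cols
  ))
  structure(
    list(
      design = design, tr = tr, n_volumes = n_volumes,
      regressors = reg_names, constant_cols = constant_cols,
      truncated_events = truncated
    ),
    class = "rws_fmri_design"
  )
}

#' @export
print.rws_fmri_design <- function(x, ...) {
  cat(
    "<rws_fmri_design>", x$n_volumes, "volumes @ TR =", x$tr, "s,",
    length(x$regressors), "regressors\n"
  )
  if (length(x$constant_cols)) {
    cat(" all-zero columns:", paste(x$constant_cols, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.rws_fmri_design <- function(x, ...) {
  as.matrix(x$design[, x$regressors])
}

#' Learning-rate-weighted lag weights
#'
#' `w_k = alpha * (1 - alpha)^(k - 1)`: the contribution of the reward `k`
#' trials back to the current Rescorla-Wagner expectation.
#'
#' @param alpha Learning rate.
#' @param n_lags Number of lags.
#' @param start_lag First lag carrying weight (2 for the variant that
#'   leaves out the most recent outcome; weights then restart the geometric
#'   decay at `start_lag`).
#' @return Numeric vector of length `n_lags - start_lag + 1`.
#' @export
rw_lag_weights <- function(alpha, n_lags = 5, start_lag = 1) {
  alpha * (1 - alpha)^(seq(start_lag, n_lags) - start_lag)
}

#' Convolve arbitrary amplitude-modulated events with the HRF
#'
#' Places impulses of the given amplitudes on the fine grid, convolves with
#' the gamma kernel and samples at the TR. Used to build signal components
#' that are not linear in the standard regressors (e.g. an unsigned
#' prediction-error signal).
#'
#' @param times Event times (s).
#' @param amplitudes Event amplitudes (recycled if length 1).
#' @param n_volumes,tr Sampling grid.
#' @param hrf An [hrf_spec()].
#' @return Numeric vector of length `n_volumes` (not z-scored).
#' @export
convolve_events <- function(times, amplitudes = 1, n_volumes, tr = 2.28,
                            hrf = hrf_spec()) {
  amplitudes <- rep_len(amplitudes, length(times))
  dt <- hrf$dt
  scan_end <- n_volumes * tr
  kern <- hrf_kernel(hrf)
  n_fine <- ceiling(scan_end / dt) + 1L
  stick <- numeric(n_fine)
  keep <- times >= 0 & times <= scan_end
  idx <- round(times[keep] / dt) + 1L
  amp <- amplitudes[keep]
  for (j in seq_along(idx)) stick[idx[j]] <- stick[idx[j]] + amp[j]
  conv <- fft_convolve_cols(matrix(stick, ncol = 1), kern)
  t_vol <- (seq_len(n_volumes) - 1) * tr
  conv[pmin(round(t_vol / dt) + 1L, n_fine), 1]
}

#' Contrast definitions over the session design
#'
#' * `sRPE`: current reward minus the learning-rate-weighted sum of the 5
#'   previous rewards (`w_k = alpha (1-alpha)^(k-1)`), i.e. the scalar
#'   reward prediction error.
#' * `sRPE_excl_recent`: the same contrast leaving out the most recent
#'   outcome; the geometric weights are re-anchored on lags 2--5 (controls
#'   for orofacial/gustatory correlates of the last juice delivery).
#' * `VS`: `VS_left + VS_right` combined across stimulus sides.
#' * `RRE`: the outcome-phase rare-reward regressor alone.
#'
#' @param alpha Learning rate in `(0, 1]` used to weight past rewards.
#' @param n_lags Number of lagged-reward regressors in the design.
#' @return Named list of named weight vectors (over regressor names).
#' @examples
#' define_contrasts(0.257)$sRPE
#' @export
define_contrasts <- function(alpha, n_lags = 5) {
  stopifnot(alpha > 0, alpha <= 1)
  lags <- paste0("reward_lag", seq_len(n_lags))
  srpe <- c(
    setNames(1, "reward_current"),
    setNames(-rw_lag_weights(alpha, n_lags), lags)
  )
  srpe_excl <- c(
    setNames(1, "reward_current"),
    setNames(
      -rw_lag_weights(alpha, n_lags, start_lag = 2),
      lags[-1]
    )
  )
  list(
    sRPE = srpe,
    sRPE_excl_recent = srpe_excl,
    VS = c(VS_left = 1, VS_right = 1),
    RRE = c(RRE_outcome = 1)
  )
}

#' Shared variance between two regressors
#'
#' `100 * r^2`, the percentage of variance two columns share; the design
#' diagnostic used to verify that surprise regressors are decorrelated.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Percentage in `[0, 100]` (`NA` with a warning for constant
#'   input).
#' @examples
#' shared_variance(1:10, 10:1) # 100
#' @export
shared_variance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input; shared variance undefined.")
    return(NA_real_)
  }
  100 * cor(x, y)^2
}
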