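#' Simulate an ROI BOLD time series from a design
#'
#' `y = X %*% effects + AR(1) Gaussian noise`, where `X` is the z-scored
#' convolved design. Effects are given per regressor (unnamed regressors get
#' zero). Noise is an AR(1) process scaled to marginal standard deviation
#' `noise_sd`. An optional Gaussian-weighted running-line high-pass filter
#' (cutoff 100 s) mimics the temporal filtering applied to real series.
#'
#' @param design An `rws_fmri_design`.
#' @param effects Named numeric vector of per-regressor amplitudes (BOLD
#'   a.u. per SD of regressor).
#' @param noise_sd Marginal noise SD (a.u.).
#' @param ar1_coef AR(1) coefficient (0.3 default; 0 gives white noise).
#' @param seed Integer seed (`NULL` for the current stream).
#' @param highpass_s High-pass cutoff (s), or `NULL` to skip filtering.
#' @return A tibble of class `rws_roi_ts` with `volume`, `time`, `bold`;
#'   attributes `"tr"`, `"effects"`.
#' @export
simulate_roi_bold <- function(design, effects = numeric(0), noise_sd = 1,
                              ar1_coef = 0.3, seed = NULL,
                              highpass_s = NULL) {
  stopifnot(inherits(design, "rws_fmri_design"))
  X <- as.matrix(design)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(effects), colnames(X))
  if (length(unknown)) {
    abort(paste("Unknown regressor(s) in `effects`:", paste(unknown, collapse = ", ")))
  }
  beta[names(effects)] <- effects
  mu <- drop(X %*% beta)
  n <- nrow(X)
  noise <- with_seed_(seed, {
    if (noise_sd == 0) {
      numeric(n)
    } else if (ar1_coef == 0) {
      rnorm(n, sd = noise_sd)
    } else {
      e <- as.numeric(arima.sim(list(ar = ar1_coef), n))
      e * noise_sd * sqrt(1 - ar1_coef^2) # unit innovations -> marginal sd
    }
  })
  y <- mu + noise
  if (!is.null(highpass_s)) {
    y <- y - lowpass_gaussian(y, design$tr, highpass_s)
  }
  out <- tibble(volume = seq_len(n), time = design$design$time, bold = y)
  attr(out, "tr") <- design$tr
  attr(out, "effects") <- effects
  class(out) <- c("rws_roi_ts", class(out))
  out
}

# Gaussian running-line smoother used as the low-frequency component of the
# high-pass filter (sigma = cutoff / 2, in seconds).
lowpass_gaussian <- function(y, tr, cutoff_s) {
  sigma <- cutoff_s / 2 / tr
  half <- ceiling(3 * sigma)
  w <- exp(-0.5 * ((-half:half) / sigma)^2)
  w <- w / sum(w)
  n <- length(y)
  padded <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(padded, w, sides = 2))[(half + 1):(half + n)]
}

#' Fit the session-level GLM to an ROI time series
#'
#' Ordinary least squares of the BOLD series on the z-scored design (plus an
#' intercept). Contrast effects are `w' b` with variance
#' `sigma^2 w' (X'X)^{-1} w`; z-statistics use the normal approximation to
#' the t distribution (session dfs are several hundred volumes), with an
#' exact-t option. Rank-deficient designs drop aliased columns with a
#' warning.
#'
#' @param ts An `rws_roi_ts` tibble (or numeric vector of BOLD values).
#' @param design The `rws_fmri_design` the series was sampled under.
#' @param contrasts Named list of contrast weight vectors (see
#'   [define_contrasts()]); weights for regressors missing from the design
#'   are treated as zero.
#' @param exact_t If TRUE, p-values use the t distribution at the residual
#'   df instead of the normal approximation.
#' @return A list of class `rws_session_glm`: `betas` (tibble), `contrasts`
#'   (tibble: contrast, effect, se, z, p), `sigma`, `df_residual`,
#'   `dropped_cols`.
#' @export
fit_session_glm <- function(ts, design, contrasts = NULL, exact_t = FALSE) {
  stopifnot(inherits(design, "rws_fmri_design"))
  y <- if (is.numeric(ts)) ts else ts$bold
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  stopifnot(length(y) == nrow(X))
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warn(paste(
      "Design is rank deficient; dropping:",
      paste(dropped, collapse = ", ")
    ))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  df_res <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrX))
  rownames(xtx_inv) <- colnames(xtx_inv) <- colnames(X)
  se_b <- sqrt(sigma2 * diag(xtx_inv))
  betas <- tibble(
    term = colnames(X), estimate = unname(b), se = unname(se_b)
  )
  ctr <- NULL
  if (!is.null(contrasts)) {
    ctr <- bind_rows(lapply(names(contrasts), function(nm) {
      w_named <- contrasts[[nm]]
      w <- setNames(numeric(ncol(X)), colnames(X))
      hit <- intersect(names(w_named), colnames(X))
      w[hit] <- w_named[hit]
      eff <- sum(w * b)
      v <- sigma2 * drop(t(w) %*% xtx_inv %*% w)
      se <- sqrt(v)
      z <- if (se > 0) eff / se else 0
      p <- if (exact_t) 2 * pt(-abs(z), df_res) else 2 * pnorm(-abs(z))
      tibble(contrast = nm, effect = eff, se = se, z = z, p = p)
    }))
  }
  structure(
    list(
      betas = betas, contrasts = ctr, sigma = sqrt(sigma2),
      df_residual = df_res, dropped_cols = dropped
    ),
    class = "rws_session_glm"
  )
}

#' @export
print.rws_session_glm <- function(x, ...) {
  cat(
    "<rws_session_glm> df =", x$df_residual,
    " sigma =", format(x$sigma, digits = 4), "\n"
  )
  if (!is.null(x$contrasts)) print(as.data.frame(x$contrasts), digits = 3)
  invisible(x)
}

#' Combine session-level effects across sessions and subjects
#'
#' Two-level summary-statistics combination: sessions are pooled within each
#' subject by precision-weighted fixed effects (subject effect = inverse-
#' variance-weighted mean of its session effects), then subjects are
#' combined by a one-sample random-effects t-test of the subject means
#' against zero (`df = n_subjects - 1`). This is a simplified summary-
#' statistics stand-in for a full Bayesian mixed-effects combination, and is
#' declared as such in the result metadata.
#'
#' @param session_results A tibble with columns `subject`, `session`,
#'   `contrast`, `effect`, `se` (one row per session x contrast), e.g. built
#'   from [fit_session_glm()] outputs.
#' @return A tibble of class `rws_group` with one row per contrast:
#'   `contrast`, `group_effect`, `t`, `df`, `p`, `n_subjects`, `flagged`
#'   (degenerate zero-variance case, t capped at +/-Inf). Subject-level
#'   effects are kept in attribute `"subject_effects"`; attribute
#'   `"method"` records the combination scheme.
#' @export
combine_levels <- function(session_results) {
  need <- c("subject", "session", "contrast", "effect", "se")
  stopifnot(all(need %in% names(session_results)))
  if (length(unique(session_results$subject)) < 2) {
    abort("Need >= 2 subjects for the group level.")
  }
  subj <- session_results %>%
    group_by(.data$subject, .data$contrast) %>%
    summarise(
      effect = {
        w <- 1 / .data$se^2
        sum(w * .data$effect) / sum(w)
      },
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n_sessions = n(),
      .groups = "drop"
    )
  grp <- subj %>%
    group_by(.data$contrast) %>%
    summarise(
      group_effect = mean(.data$effect),
      sd_effect = sd(.data$effect),
      n_subjects = n(),
      .groups = "drop"
    ) %>%
    mutate(
      flagged = .data$sd_effect == 0,
      t = ifelse(.data$flagged,
        ifelse(.data$group_effect == 0, 0, Inf * sign(.data$group_effect)),
        .data$group_effect / (.data$sd_effect / sqrt(.data$n_subjects))
      ),
      df = .data$n_subjects - 1,
      p = ifelse(.data$flagged,
        ifelse(.data$group_effect == 0, 1, 0),
        2 * pt(-abs(.data$t), .data$n_subjects - 1)
      )
    ) %>%
    select("contrast", "group_effect", "t", "df", "p", "n_subjects", "flagged")
  attr(grp, "subject_effects") <- subj
  attr(grp, "method") <- "sessions: precision-weighted fixed effects; subjects: one-sample random-effects t"
  class(grp) <- c("rws_group", class(grp))
  grp
}

#' Extract peristimulus epoch averages from an ROI time series
#'
#' The series is up-sampled by a factor of 10 with spline interpolation,
#' epochs are cut at the supplied onsets, baselined at onset, and averaged
#' over `avg_window` (0--10 s by default) to give one value per event,
#' optionally split by a per-event factor such as the delivered drops.
#' Epochs overrunning the scan are excluded (count reported in attribute
#' `"n_excluded"`).
#'
#' @param ts An `rws_roi_ts` tibble.
#' @param onsets Event onset times (s).
#' @param split Optional per-event labels (e.g. drops) of the same length
#'   as `onsets`.
#' @param window_s Epoch length (s).
#' @param avg_window Length-2 window (s) over which each epoch is averaged.
#' @param upsample Up-sampling factor for the spline interpolation.
#' @return A list of class `rws_timecourse`: `epochs` (tibble: `event`,
#'   `split`, `epoch_mean`), `timecourse` (tibble: `split`, `t_rel`,
#'   `mean_bold` averaged over events), `n_excluded`.
#' @export
extract_timecourse <- function(ts, onsets, split = NULL, window_s = 12,
                               avg_window = c(0, 10), upsample = 10) {
  tr <- attr(ts, "tr")
  if (is.null(tr)) tr <- diff(ts$time[1:2])
  stopifnot(window_s >= tr, length(avg_window) == 2)
  if (is.null(split)) split <- rep("all", length(onsets))
  stopifnot(length(split) == length(onsets))
  t_max <- max(ts$time)
  ok <- onsets >= 0 & (onsets + window_s) <= t_max
  n_excluded <- sum(!ok)
  onsets <- onsets[ok]
  split <- split[ok]
  if (!length(onsets)) abort("No epoch fits inside the scan.")
  dt_up <- tr / upsample
  rel <- seq(0, window_s, by = dt_up)
  epoch_vals <- vapply(onsets, function(t0) {
    v <- spline(ts$time, ts$bold, xout = t0 + rel)$y
    v - v[1] # baseline at onset
  }, numeric(length(rel)))
  in_avg <- rel >= avg_window[1] & rel <= avg_window[2]
  epochs <- tibble(
    event = seq_along(onsets),
    split = split,
    epoch_mean = colMeans(epoch_vals[in_avg, , drop = FALSE])
  )
  tc <- tibble(
    split = rep(split, each = length(rel)),
    t_rel = rep(rel, length(onsets)),
    bold = as.numeric(epoch_vals)
  ) %>%
    group_by(.data$split, .data$t_rel) %>%
    summarise(mean_bold = mean(.data$bold), .groups = "drop")
  structure(
    list(epochs = epochs, timecourse = tc, n_excluded = n_excluded),
    class = "rws_timecourse"
  )
}

#' Group test of epoch averages against baseline
#'
#' Session-level epoch means are averaged per subject and tested against
#' zero with a one-sample t-test, treating subjects as random effects.
#'
#' @param epoch_table A tibble with columns `subject` and `epoch_mean`
#'   (optionally `split`; the test is run per split level).
#' @return Tibble with one row per split: `split`, `mean`, `t`, `df`, `p`.
#' @export
epoch_group_test <- function(epoch_table) {
  stopifnot(all(c("subject", "epoch_mean") %in% names(epoch_table)))
  if (!"split" %in% names(epoch_table)) epoch_table$split <- "all"
  epoch_table %>%
    group_by(.data$split, .data$subject) %>%
    summarise(m = mean(.data$epoch_mean), .groups = "drop") %>%
    group_by(.data$split) %>%
    summarise(
      mean = mean(.data$m),
      t = ifelse(sd(.data$m) == 0, ifelse(mean(.data$m) == 0, 0, Inf),
        mean(.data$m) / (sd(.data$m) / sqrt(n()))
      ),
      df = n() - 1,
      p = 2 * pt(-abs(.data$t), n() - 1),
      .groups = "drop"
    )
}
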