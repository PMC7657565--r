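#' Build the trial-level design for the lapse and RT models
#'
#' Constructs the z-scored predictor matrix used by the behavioural models.
#' Per attempt: `vs` (stimulus side differs from the previous attempt's
#' side, zeroed on attempts that follow an error because the trial repeats
#' unchanged), `rre` (the previous rewarded trial delivered 2 drops, zeroed
#' after errors; `rre_lag = 0` uses the current trial's outcome instead),
#' `position` (right = 1), `trialno`, and either a single `sre` column (the
#' Rescorla-Wagner expectation under `alpha`) or five lagged-reward columns
#' `r_lag1` ... `r_lag5`. Trials with fewer than `n_lags` preceding rewarded
#' trials are dropped. All predictors are z-scored per session; zero-variance
#' columns are left at zero and recorded in the `"constant_cols"` attribute.
#'
#' @param trials An `rws_trials` tibble (or several sessions bound together
#'   with `subject` and `session` columns; both default to `"s1"` if
#'   absent).
#' @param alpha If non-`NULL`, build the single `sre` column with this
#'   learning rate; otherwise build the five lagged-reward columns.
#' @param n_lags Number of reward lags (5).
#' @param rre_lag 1 (default; previous-trial outcome, available at decision
#'   time) or 0 (current-trial outcome).
#' @param zscore_scope `"session"` (default) or `"none"`.
#' @return A tibble of class `rws_design` with identifier columns, the
#'   binary `response` (error or outlier), `rt_ms`, and the predictor
#'   columns. Attributes: `"predictors"`, `"n_dropped"`, `"constant_cols"`.
#' @export
build_behavior_design <- function(trials, alpha = NULL, n_lags = 5,
                                  rre_lag = 1,
                                  zscore_scope = c("session", "none")) {
  zscore_scope <- match.arg(zscore_scope)
  stopifnot(rre_lag %in% c(0, 1), n_lags >= 1)
  df <- as_tibble(trials)
  if (!"subject" %in% names(df)) df$subject <- "s1"
  if (!"session" %in% names(df)) df$session <- "s1"
  if (!"is_outlier" %in% names(df)) {
    df$is_outlier <- label_outliers(df$rt_ms)
  }
  n_in <- nrow(df)
  parts <- lapply(split(df, paste(df$subject, df$session, sep = "\r")), function(d) {
    d <- d[order(d$trial, d$attempt), ]
    # rewarded-trial reward sequence for this session (drops on the correct
    # attempt of each trial)
    ok <- !is.na(d$drops) & !d$is_error
    rew <- d$drops[ok][order(d$trial[ok])]
    ntr <- length(rew)
    # per-trial lagged rewards; lag k of trial t is the reward on trial t-k
    lagmat <- sapply(seq_len(n_lags), function(k) {
      c(rep(NA_real_, k), rew)[seq_len(ntr)]
    })
    if (is.null(dim(lagmat))) lagmat <- matrix(lagmat, nrow = ntr)
    d$response <- as.integer(d$is_error | d$is_outlier)
    d$position <- as.integer(d$side == "right")
    d$trialno <- d$trial
    if (rre_lag == 0) {
      # current-trial outcome; still zeroed on repeated attempts
      d$rre <- ifelse(d$attempt > 1, 0L, as.integer(rew[d$trial] == 2))
    } else {
      if (!"rre_prev" %in% names(d)) {
        rre_by_trial <- c(0L, as.integer(rew[-ntr] == 2))
        d$rre_prev <- ifelse(d$attempt > 1, 0L, rre_by_trial[d$trial])
      }
      d$rre <- as.integer(d$rre_prev)
    }
    if (!"vs_zeroed" %in% names(d)) {
      side_by_trial <- d$side[d$attempt == 1][order(d$trial[d$attempt == 1])]
      vs_by_trial <- c(
        0L,
        as.integer(side_by_trial[-1] != side_by_trial[-ntr])
      )
      d$vs_zeroed <- ifelse(d$attempt > 1, 0L, vs_by_trial[d$trial])
    }
    d$vs <- as.integer(d$vs_zeroed)
    if (!is.null(alpha)) {
      v <- compute_sre(rew, alpha, v0 = 2)[seq_len(ntr)]
      d$sre <- v[d$trial]
    } else {
      for (k in seq_len(n_lags)) {
        d[[paste0("r_lag", k)]] <- lagmat[d$trial, k]
      }
    }
    d[d$trial > n_lags, ]
  })
  out <- bind_rows(parts)
  preds <- c(
    "vs",
    if (!is.null(alpha)) "sre" else paste0("r_lag", seq_len(n_lags)),
    "rre", "position", "trialno"
  )
  constant_cols <- character(0)
  if (zscore_scope == "session") {
    out <- out %>%
      group_by(.data$subject, .data$session) %>%
      mutate(across(all_of(preds), zscore)) %>%
      ungroup()
  }
  for (p in preds) {
    if (sd(out[[p]]) == 0) constant_cols <- c(constant_cols, p)
  }
  if (length(constant_cols)) {
    warn(paste(
      "Zero-variance predictor column(s):",
      paste(constant_cols, collapse = ", "),
      "- excluded from model fits."
    ))
  }
  keep <- c(
    "subject", "session", "trial", "attempt", "response", "rt_ms",
    "is_error", "is_outlier", preds
  )
  out <- out[, intersect(keep, names(out))]
  attr(out, "predictors") <- setdiff(preds, constant_cols)
  attr(out, "constant_cols") <- constant_cols
  attr(out, "n_dropped") <- n_in - nrow(out)
  attr(out, "alpha") <- alpha
  class(out) <- c("rws_design", class(out))
  out
}

design_predictors <- function(design, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- attr(design, "predictors")
  }
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(design),
      c(
        "subject", "session", "trial", "attempt", "response", "rt_ms",
        "is_error", "is_outlier"
      )
    )
  }
  predictors
}

# Aggregate per-subject GLM fits by inverse-variance weighting. Subjects
# whose fit failed or was degenerate (separation: |coef| or SE blown up) get
# inflated SEs via the `degenerate` flag on the subject table.
aggregate_subject_fits <- function(fits, terms) {
  per <- bind_rows(lapply(names(fits), function(s) {
    f <- fits[[s]]
    if (is.null(f)) {
      return(NULL)
    }
    est <- coef(f)
    se <- sqrt(diag(vcov(f)))
    tibble(
      subject = s, term = names(est), estimate = unname(est),
      se = unname(se),
      degenerate = unname(!is.finite(se) | se > 50 | abs(est) > 50)
    )
  }))
  pop <- per %>%
    group_by(.data$term) %>%
    summarise(
      estimate = {
        w <- ifelse(.data$degenerate, 0, 1 / .data$se^2)
        if (sum(w) == 0) mean(.data$estimate) else sum(w * .data$estimate) / sum(w)
      },
      se = {
        w <- ifelse(.data$degenerate, 0, 1 / .data$se^2)
        if (sum(w) == 0) Inf else 1 / sqrt(sum(w))
      },
      n_subjects = n(),
      .groups = "drop"
    ) %>%
    mutate(
      z = .data$estimate / .data$se,
      p = 2 * pnorm(-abs(.data$z))
    )
  pop <- pop[match(terms, pop$term), ]
  list(population = pop, per_subject = per)
}

#' Fit the hierarchical logistic lapse model
#'
#' Models the binary lapse outcome (error or outlier RT) as a logistic
#' function of the design's predictors. `method = "glmer"` fits the full
#' mixed model with random slopes for every subject and a random intercept
#' for every session (lme4). Because full random-slope binomial fits are
#' fragile on small cohorts, the default `"per_subject"` method fits one
#' maximum-likelihood logistic regression per subject and aggregates
#' coefficients by inverse-variance weighting; `"auto"` tries the mixed
#' model first and falls back. The fitting route is recorded in the result.
#'
#' @param design An `rws_design` tibble from [build_behavior_design()].
#' @param predictors Optional character vector of predictor columns
#'   (default: all non-constant predictors in the design). Use this to fit
#'   reduced models for [lr_test()].
#' @param method `"per_subject"`, `"glmer"` or `"auto"`.
#' @return An object of class `rws_fit` with elements `coefficients`
#'   (tibble: term, estimate, se, z, p), `logLik`, `df_model`, `n_obs`,
#'   `method`, `per_subject`, `converged`, `family`, `predictors`.
#' @export
fit_lapse_model <- function(design,
                            predictors = NULL,
                            method = c("per_subject", "glmer", "auto")) {
  method <- match.arg(method)
  predictors <- design_predictors(design, predictors)
  fit_glm_family(design,
    predictors = predictors, method = method,
    family = binomial(), response = "response"
  )
}

#' Fit the reaction-time model (gamma, log link)
#'
#' Same predictor sets and hierarchical structure as the lapse model, with
#' RT (ms) as the dependent variable, a gamma error distribution and a log
#' link. `exclude = "outliers"` removes outlier attempts only; `"lapses"`
#' additionally removes errors and the repeated attempts that follow them.
#'
#' @inheritParams fit_lapse_model
#' @param exclude `"outliers"` or `"lapses"` (outliers + errors + repeats).
#' @return An `rws_fit` object (see [fit_lapse_model()]).
#' @export
fit_rt_model <- function(design, predictors = NULL,
                         exclude = c("outliers", "lapses"),
                         method = c("per_subject", "glmer", "auto")) {
  method <- match.arg(method)
  exclude <- match.arg(exclude)
  predictors <- design_predictors(design, predictors)
  keep <- !design$is_outlier
  if (exclude == "lapses") {
    keep <- keep & !design$is_error & design$attempt == 1
  }
  d <- design[keep, ]
  if (any(d$rt_ms <= 0)) abort("Nonpositive RTs cannot be fit with a log link.")
  fit_glm_family(d,
    predictors = predictors, method = method,
    family = Gamma(link = "log"), response = "rt_ms"
  )
}

fit_glm_family <- function(design, predictors, method, family, response) {
  dat <- as_tibble(design)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml_fixed <- as.formula(paste(response, "~", rhs))
  terms <- c("(Intercept)", predictors)
  fit <- NULL
  used <- method
  converged <- TRUE
  if (method %in% c("glmer", "auto") && length(unique(dat$subject)) >= 2) {
    rs <- paste(predictors, collapse = " + ")
    fml <- as.formula(paste(
      response, "~ 1 +", rs,
      "+ (1 +", rs, "| subject) + (1 | subject:session)"
    ))
    res <- tryCatch(
      {
        m <- lme4::glmer(fml,
          data = dat, family = family, nAGQ = 0,
          control = lme4::glmerControl(
            optimizer = "bobyqa",
            calc.derivs = FALSE
          )
        )
        sm <- summary(m)$coefficients
        per_sub <- tryCatch(
          {
            ce <- coef(m)$subject
            ce$subject <- rownames(ce)
            as_tibble(ce) %>%
              tidyr::pivot_longer(-"subject",
                names_to = "term",
                values_to = "estimate"
              )
          },
          error = function(e) NULL
        )
        list(
          population = tibble(
            term = rownames(sm), estimate = unname(sm[, 1]),
            se = unname(sm[, 2]),
            n_subjects = length(unique(dat$subject))
          ) %>% mutate(z = .data$estimate / .data$se, p = 2 * pnorm(-abs(.data$z))),
          per_subject = per_sub,
          logLik = as.numeric(logLik(m)),
          model = m
        )
      },
      error = function(e) NULL,
      warning = function(w) NULL
    )
    if (!is.null(res)) {
      fit <- res
      used <- "glmer"
    } else if (method == "glmer") {
      warn("glmer fit failed; falling back to per-subject aggregation.")
      used <- "per_subject"
    } else {
      used <- "per_subject"
    }
  } else if (method != "per_subject") {
    used <- "per_subject"
  }
  if (is.null(fit)) {
    subs <- split(dat, dat$subject)
    fits <- lapply(subs, function(d) {
      tryCatch(
        suppressWarnings(glm(fml_fixed, data = d, family = family)),
        error = function(e) NULL
      )
    })
    converged <- all(vapply(
      fits[!vapply(fits, is.null, TRUE)],
      function(f) isTRUE(f$converged), TRUE
    ))
    agg <- aggregate_subject_fits(fits, terms)
    ll <- sum(vapply(fits, function(f) {
      if (is.null(f)) 0 else as.numeric(logLik(f))
    }, 0))
    fit <- list(
      population = agg$population, per_subject = agg$per_subject,
      logLik = ll, model = NULL
    )
  }
  structure(
    list(
      coefficients = fit$population,
      per_subject = fit$per_subject,
      logLik = fit$logLik,
      df_model = length(terms),
      n_obs = nrow(dat),
      method = used,
      converged = converged,
      family = family$family,
      predictors = predictors,
      model = fit$model
    ),
    class = "rws_fit"
  )
}

#' @export
print.rws_fit <- function(x, ...) {
  cat(
    "<rws_fit> ", x$family, " model, method = ", x$method,
    ", n = ", x$n_obs, ", logLik = ", format(x$logLik, digits = 6), "\n",
    sep = ""
  )
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi2 = 2 * (logLik(full) - logLik(reduced))`, clipped at zero, referred
#' to a chi-squared distribution with `df` degrees of freedom. For the
#' scalar-reward-expectation term, `df = 2` accounts for the learning rate
#' and the scale fitted upstream of the regression.
#'
#' @param full,reduced `rws_fit` objects; `reduced`'s predictors must be a
#'   subset of `full`'s and both must be fit to the same observations.
#' @param df Test degrees of freedom; defaults to the difference in the
#'   number of model terms.
#' @return A tibble with `chi2`, `df`, `p`.
#' @examples
#' # pchisq gives p ~ 0.05 at chi2 = 3.84, df = 1
#' pchisq(3.84, 1, lower.tail = FALSE)
#' @export
lr_test <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "rws_fit"), inherits(reduced, "rws_fit"))
  if (!all(reduced$predictors %in% full$predictors)) {
    abort("`reduced` is not nested in `full` (predictors are not a subset).")
  }
  if (full$n_obs != reduced$n_obs) {
    abort("Models were fit to different numbers of observations.")
  }
  if (is.null(df)) df <- full$df_model - reduced$df_model
  if (df < 1) abort("`df` must be >= 1.")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Learning rate from lagged-reward regression weights (truncated RW fit)
#'
#' The influence of the reward `k` trials back on the current expectation
#' under a Rescorla-Wagner learner with learning rate `alpha` is
#' `w_k = c * alpha * (1 - alpha)^(k-1)`, where `c` is a free multiplicative
#' scale (the inverse-temperature analogue). Given the five regression
#' weights on lagged rewards, this finds the `(alpha, c)` minimising the
#' Euclidean norm between model and observed weights: a 1001-point grid on
#' `[0, 1]` with the scale solved in closed form per grid point
#' (least-squares projection), then golden-section refinement.
#'
#' @param lag_betas Numeric vector of exactly 5 regression weights
#'   (lag 1 ... lag 5).
#' @param n_grid Number of grid points on `[0, 1]`.
#' @return A list of class `rws_rwfit`: `alpha_hat`, `scale_hat`,
#'   `residual_norm`, `flagged` (TRUE when the input is degenerate, e.g.
#'   all-zero weights).
#' @examples
#' w <- 0.6 * 0.257 * (1 - 0.257)^(0:4)
#' fit_truncated_rw(w)$alpha_hat
#' @export
fit_truncated_rw <- function(lag_betas, n_grid = 1001) {
  if (length(lag_betas) != 5 || any(!is.finite(lag_betas))) {
    abort("`lag_betas` must be 5 finite values.")
  }
  b <- as.numeric(lag_betas)
  if (all(b == 0)) {
    return(structure(
      list(
        alpha_hat = NA_real_, scale_hat = 0,
        residual_norm = 0, flagged = TRUE
      ),
      class = "rws_rwfit"
    ))
  }
  k <- 0:4
  obj <- function(a) {
    w <- a * (1 - a)^k
    ss <- sum(w^2)
    if (ss == 0) {
      return(c(res = sqrt(sum(b^2)), cc = 0))
    }
    cc <- sum(b * w) / ss
    c(res = sqrt(sum((b - cc * w)^2)), cc = cc)
  }
  grid <- seq(0, 1, length.out = n_grid)
  res <- vapply(grid, function(a) obj(a)[["res"]], 0)
  i <- which.min(res)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(function(a) obj(a)[["res"]], c(lo, hi), tol = 1e-10)
  # keep the grid point if refinement did not improve (flat boundaries)
  if (opt$objective <= res[i]) {
    a_hat <- opt$minimum
    r <- opt$objective
  } else {
    a_hat <- grid[i]
    r <- res[i]
  }
  o <- obj(a_hat)
  structure(
    list(
      alpha_hat = a_hat, scale_hat = o[["cc"]],
      residual_norm = o[["res"]], flagged = FALSE
    ),
    class = "rws_rwfit"
  )
}

#' @export
print.rws_rwfit <- function(x, ...) {
  cat(
    "<rws_rwfit> alpha =", format(x$alpha_hat, digits = 4),
    " scale =", format(x$scale_hat, digits = 4),
    " residual =", format(x$residual_norm, digits = 4),
    if (x$flagged) " [flagged]" else "", "\n"
  )
  invisible(x)
}

#' Reward-history slope test
#'
#' Fits an ordinary least-squares line through each subject's five
#' lagged-reward beta weights as a function of lag (1 ... 5) and tests the
#' per-subject slopes against zero with a one-sample t-test
#' (`df = n_subjects - 1`). A decaying influence of past rewards appears as
#' a consistent nonzero slope.
#'
#' @param per_subject_lag_betas Numeric matrix (subjects x 5) or a tibble
#'   with columns `subject`, `term` (`r_lag1` ... `r_lag5`), `estimate`.
#' @return A tibble with `t`, `df`, `p`, `mean_slope`, `n_subjects`, and a
#'   `flagged` column set when the slopes have zero variance.
#' @export
reward_history_slope_test <- function(per_subject_lag_betas) {
  x <- per_subject_lag_betas
  if (is.data.frame(x)) {
    lag_terms <- paste0("r_lag", 1:5)
    x <- x %>%
      filter(.data$term %in% lag_terms) %>%
      tidyr::pivot_wider(
        id_cols = "subject", names_from = "term",
        values_from = "estimate"
      )
    x <- as.matrix(x[, lag_terms])
  }
  x <- as.matrix(x)
  if (ncol(x) != 5) abort("Expected 5 lag columns.")
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    warn(sprintf("%d subject(s) with missing betas excluded.", sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 2) abort("Need >= 2 subjects with complete betas.")
  lag <- 1:5
  slopes <- apply(x, 1, function(bb) {
    sum((lag - mean(lag)) * (bb - mean(bb))) / sum((lag - mean(lag))^2)
  })
  if (sd(slopes) == 0) {
    return(tibble(
      t = ifelse(mean(slopes) == 0, 0, Inf), df = length(slopes) - 1,
      p = ifelse(mean(slopes) == 0, 1, 0),
      mean_slope = mean(slopes), n_subjects = length(slopes), flagged = TRUE
    ))
  }
  tt <- t.test(slopes, mu = 0)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_slope = mean(slopes),
    n_subjects = length(slopes), flagged = FALSE
  )
}
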