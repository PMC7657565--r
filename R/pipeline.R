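#' Configure a simulated cohort
#'
#' Bundles everything needed to reproduce a full simulated experiment:
#' subjects, sessions per schedule type (defaults mirror the study design:
#' 6 stable, 2 + 2 changing, 2 equiprobable sessions per subject), the
#' generative agent, the ROI effect map, and noise levels. The same config
#' and seed always produce identical outputs.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param sessions_per_type Named integer vector with entries `stable`,
#'   `changing_up`, `changing_down`, `equiprobable`.
#' @param n_trials Rewarded trials per session (default 150).
#' @param seed Master seed; all stage seeds are derived from it (see
#'   [derive_seed()]).
#' @param agent An [agent_params()] object.
#' @param roi_effects Named list of ROI specifications, each a list with
#'   `pattern` (`"sRPE"`, `"RRE"`, `"VS"`, `"magnitude"`, `"abs_sRPE"` or
#'   `"none"`), `amplitude` (BOLD a.u. per regressor SD), and optionally
#'   `session_types` (restrict the injected effect to some schedule types).
#' @param noise_sd,ar1_coef ROI noise parameters.
#' @param tr Repetition time (s).
#' @param alpha_design Learning rate for design contrasts when the fitted
#'   one is not used.
#' @param alpha_sig Two-sided significance level used to call group effects
#'   in the dissociation report (0.01: stringent, in the spirit of corrected
#'   neuroimaging inference rather than nominal 0.05).
#' @param fit_method Method passed to [fit_lapse_model()].
#' @return A list of class `rws_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6,
                          sessions_per_type = c(
                            stable = 6, changing_up = 2,
                            changing_down = 2, equiprobable = 2
                          ),
                          n_trials = 150,
                          seed = 1,
                          agent = agent_params(),
                          roi_effects = default_roi_effects(),
                          noise_sd = 1,
                          ar1_coef = 0.3,
                          tr = 2.28,
                          alpha_design = 0.257,
                          alpha_sig = 0.01,
                          fit_method = "per_subject") {
  types <- c("stable", "changing_up", "changing_down", "equiprobable")
  stopifnot(
    n_subjects >= 1,
    all(names(sessions_per_type) %in% types),
    all(sessions_per_type >= 0),
    n_trials > 5
  )
  full <- setNames(rep(0L, length(types)), types)
  full[names(sessions_per_type)] <- as.integer(sessions_per_type)
  structure(
    list(
      n_subjects = n_subjects, sessions_per_type = full,
      n_trials = as.integer(n_trials), seed = seed, agent = agent,
      roi_effects = roi_effects, noise_sd = noise_sd, ar1_coef = ar1_coef,
      tr = tr, alpha_design = alpha_design, alpha_sig = alpha_sig,
      fit_method = fit_method
    ),
    class = "rws_cohort_config"
  )
}

#' Default ROI effect map
#'
#' Three synthetic regions mirroring the dissociation of interest: a
#' midbrain/striatum-like ROI carrying a signed scalar reward prediction
#' error, a posterior-lateral-OFC-like ROI carrying the rare-reward effect
#' (in changing/learnable sessions only, where the reward statistics can be
#' learned), and a lateral-prefrontal-like ROI carrying visuospatial
#' surprise.
#'
#' @param amplitude Effect amplitude (BOLD a.u. per regressor SD).
#' @return Named list usable as `roi_effects` in [cohort_config()].
#' @export
default_roi_effects <- function(amplitude = 0.2) {
  list(
    vta_striatum = list(pattern = "sRPE", amplitude = amplitude),
    plofc = list(
      pattern = "RRE", amplitude = amplitude,
      session_types = c("changing_up", "changing_down")
    ),
    lpfc = list(pattern = "VS", amplitude = amplitude)
  )
}

# Per-regressor amplitude vector for a named effect pattern.
roi_effect_vector <- function(pattern, amplitude, alpha, n_lags = 5) {
  switch(pattern,
    none = setNames(numeric(0), character(0)),
    sRPE = c(
      setNames(amplitude, "reward_current"),
      setNames(-amplitude * rw_lag_weights(alpha, n_lags),
        paste0("reward_lag", seq_len(n_lags))
      )
    ),
    RRE = c(RRE_outcome = amplitude),
    VS = c(VS_left = amplitude, VS_right = amplitude),
    magnitude = c(reward_current = amplitude),
    abs_sRPE = setNames(numeric(0), character(0)), # handled as custom signal
    abort(paste("Unknown ROI effect pattern:", pattern))
  )
}

session_type_of <- function(spec) spec$session_type

#' Simulate a full cohort
#'
#' Generates every session and the agent's behaviour on it, with seeds
#' derived per subject, session and stage from the master seed.
#'
#' @param config An [cohort_config()] object.
#' @return A list of class `rws_cohort`: `sessions` (list of records with
#'   `subject`, `session`, `session_type`, `session_tbl`, `trials`) and
#'   `trials` (all attempts bound, with `subject`/`session` columns).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "rws_cohort_config"))
  recs <- list()
  for (i in seq_len(config$n_subjects)) {
    sub <- sprintf("m%02d", i)
    for (type in names(config$sessions_per_type)) {
      k <- config$sessions_per_type[[type]]
      if (k == 0) next
      for (j in seq_len(k)) {
        ses <- sprintf("%s_%s%02d", sub, type, j)
        spec <- schedule_spec(type, n_rewarded_trials = config$n_trials)
        s_tbl <- generate_session(
          spec,
          seed = derive_seed(config$seed, sub, type, j, "schedule")
        )
        tr <- simulate_behavior(
          s_tbl, config$agent,
          seed = derive_seed(config$seed, sub, type, j, "behavior")
        )
        tr$subject <- sub
        tr$session <- ses
        recs[[ses]] <- list(
          subject = sub, session = ses, session_type = type,
          session_tbl = s_tbl, trials = tr
        )
      }
    }
  }
  structure(
    list(
      sessions = recs,
      trials = bind_rows(lapply(recs, function(r) r$trials))
    ),
    class = "rws_cohort"
  )
}

#' Trial-level surprise regressors for one reward sequence
#'
#' The trial-level (pre-convolution) scalar reward prediction error
#' `srpe = r_t - sum_k w_k r_(t-k)` with `w_k = alpha (1-alpha)^(k-1)`, and
#' the rare-reward indicator `rre = (r_t == 2)`. The first `n_lags` trials,
#' which lack a full reward history, are dropped.
#'
#' @param drops Reward sequence (drops).
#' @param alpha Learning rate.
#' @param n_lags Number of lags.
#' @return Tibble with `trial`, `srpe`, `rre`.
#' @export
trial_level_srpe <- function(drops, alpha = 0.257, n_lags = 5) {
  n <- length(drops)
  stopifnot(n > n_lags)
  w <- rw_lag_weights(alpha, n_lags)
  idx <- (n_lags + 1):n
  expect <- vapply(idx, function(t) sum(w * drops[t - seq_len(n_lags)]), 0)
  tibble(
    trial = idx,
    srpe = drops[idx] - expect,
    rre = as.integer(drops[idx] == 2)
  )
}

#' Pooled sRPE/RRE shared variance over simulated cohorts
#'
#' The design diagnostic at the heart of the schedule construction: across
#' a simulated cohort, the trial-level sRPE regressor (alpha-weighted, 5
#' lags) and the rare-reward indicator are pooled over all sessions of one
#' schedule class and their shared variance (`100 r^2`) computed, once per
#' master seed.
#'
#' @param session_class `"stable"` (6 sessions/subject), `"changing"`
#'   (2 up + 2 down), or `"equiprobable"` (2).
#' @param n_subjects Subjects per cohort.
#' @param n_trials Rewarded trials per session.
#' @param alpha Learning rate for the sRPE weights.
#' @param seeds Integer vector of master seeds (one pooled value each).
#' @return Tibble with `seed` and `shared_variance_pct`.
#' @export
srpe_rre_shared_variance <- function(session_class = c(
                                       "stable", "changing",
                                       "equiprobable"
                                     ),
                                     n_subjects = 6, n_trials = 150,
                                     alpha = 0.257, seeds = 1:20) {
  session_class <- match.arg(session_class)
  plan <- switch(session_class,
    stable = c(stable = 6),
    changing = c(changing_up = 2, changing_down = 2),
    equiprobable = c(equiprobable = 2)
  )
  out <- vapply(seeds, function(sd0) {
    srpe <- numeric(0)
    rre <- integer(0)
    for (i in seq_len(n_subjects)) {
      for (type in names(plan)) {
        for (j in seq_len(plan[[type]])) {
          spec <- schedule_spec(type, n_rewarded_trials = n_trials)
          drops <- generate_reward_sequence(
            spec,
            seed = derive_seed(sd0, sprintf("m%02d", i), type, j, "schedule", "rewards")
          )
          tl <- trial_level_srpe(drops, alpha)
          srpe <- c(srpe, tl$srpe)
          rre <- c(rre, tl$rre)
        }
      }
    }
    shared_variance(srpe, rre)
  }, 0)
  tibble(seed = seeds, shared_variance_pct = out)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes: cohort simulation; the behavioural stack (lagged-reward lapse
#' model, truncated-RW learning-rate estimate, reward-history slope test,
#' sRE lapse model with likelihood-ratio test, optional RT model); trial-
#' level design diagnostics (pooled shared variance between surprise
#' regressors per schedule class); fMRI simulation and fitting for every
#' session and ROI; and two-level group combination per ROI, contrast, and
#' session scope. Stage failures abort with a stage-tagged error.
#'
#' @param config An [cohort_config()] object.
#' @param do_behavior,do_fmri,do_rt Stage switches.
#' @return A list of class `rws_pipeline`: `cohort`, `behavior`,
#'   `diagnostics`, `fmri_sessions`, `dissociation`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), do_behavior = TRUE,
                         do_fmri = TRUE, do_rt = FALSE) {
  stopifnot(inherits(config, "rws_cohort_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[stage ", name, "] ", conditionMessage(e)))
    })
  }
  t0 <- Sys.time()
  walltimes <- list()
  cohort <- stage("simulate", simulate_cohort(config))
  walltimes$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  behavior <- NULL
  alpha_used <- config$alpha_design
  if (do_behavior) {
    tb <- Sys.time()
    behavior <- stage("behavior", {
      d_lag <- build_behavior_design(cohort$trials, alpha = NULL)
      glme2 <- fit_lapse_model(d_lag, method = config$fit_method)
      lag_terms <- paste0("r_lag", 1:5)
      pooled_betas <- glme2$coefficients$estimate[
        match(lag_terms, glme2$coefficients$term)
      ]
      # the scale is free in sign, so the (negative) lapse betas can be
      # passed directly
      rw <- fit_truncated_rw(pooled_betas)
      slope <- if (!is.null(glme2$per_subject) &&
        length(unique(glme2$per_subject$subject)) >= 2) {
        reward_history_slope_test(glme2$per_subject)
      } else {
        NULL
      }
      alpha_hat <- if (!is.na(rw$alpha_hat)) rw$alpha_hat else config$alpha_design
      d_sre <- build_behavior_design(cohort$trials, alpha = alpha_hat)
      glme1 <- fit_lapse_model(d_sre, method = config$fit_method)
      glme1_nosre <- fit_lapse_model(
        d_sre,
        predictors = setdiff(attr(d_sre, "predictors"), "sre"),
        method = config$fit_method
      )
      # 2 df: the learning rate and the scale were fit upstream
      lrt_sre <- lr_test(glme1, glme1_nosre, df = 2)
      rt_fit <- if (do_rt) fit_rt_model(d_sre, method = config$fit_method) else NULL
      list(
        glme2 = glme2, rw = rw, alpha_hat = alpha_hat,
        slope_test = slope, glme1 = glme1, lrt_sre = lrt_sre,
        rt_fit = rt_fit
      )
    })
    alpha_used <- behavior$alpha_hat
    # an implausible behavioural estimate falls back to the design default
    if (!is.finite(alpha_used) || alpha_used <= 0.01 || alpha_used >= 0.99) {
      alpha_used <- config$alpha_design
    }
    walltimes$behavior <- as.numeric(Sys.time() - tb, units = "secs")
  }

  td <- Sys.time()
  diagnostics <- stage("diagnostics", {
    bind_rows(lapply(cohort$sessions, function(r) {
      tl <- trial_level_srpe(r$session_tbl$drops, alpha_used)
      tibble(
        subject = r$subject, session = r$session,
        session_type = r$session_type,
        srpe = list(tl$srpe), rre = list(tl$rre)
      )
    })) %>%
      mutate(class = ifelse(.data$session_type %in% c("changing_up", "changing_down"),
        "changing", .data$session_type
      )) %>%
      group_by(.data$class) %>%
      summarise(
        shared_variance_pct = shared_variance(
          unlist(.data$srpe),
          unlist(.data$rre)
        ),
        n_trials = length(unlist(.data$srpe)),
        .groups = "drop"
      )
  })
  walltimes$diagnostics <- as.numeric(Sys.time() - td, units = "secs")

  fmri_sessions <- NULL
  dissociation <- NULL
  if (do_fmri) {
    tf <- Sys.time()
    fmri <- stage("fmri", {
      contrasts <- define_contrasts(alpha_used)
      rows <- list()
      for (r in cohort$sessions) {
        des <- build_fmri_design(r$session_tbl, r$trials, tr = config$tr)
        for (roi in names(config$roi_effects)) {
          eff_spec <- config$roi_effects[[roi]]
          active <- is.null(eff_spec$session_types) ||
            r$session_type %in% eff_spec$session_types
          eff <- if (active) {
            roi_effect_vector(eff_spec$pattern, eff_spec$amplitude, alpha_used)
          } else {
            setNames(numeric(0), character(0))
          }
          eff <- eff[names(eff) %in% setdiff(des$regressors, des$constant_cols)]
          ts <- simulate_roi_bold(
            des, eff,
            noise_sd = config$noise_sd, ar1_coef = config$ar1_coef,
            seed = derive_seed(config$seed, r$session, roi, "bold")
          )
          if (active && identical(eff_spec$pattern, "abs_sRPE")) {
            tl <- trial_level_srpe(r$session_tbl$drops, alpha_used)
            sig <- convolve_events(
              r$session_tbl$t_outcome[tl$trial], abs(tl$srpe),
              n_volumes = des$n_volumes, tr = config$tr
            )
            ts$bold <- ts$bold + eff_spec$amplitude * zscore(sig)
          }
          g <- fit_session_glm(ts, des, contrasts)
          cc <- g$contrasts
          cc$subject <- r$subject
          cc$session <- r$session
          cc$session_type <- r$session_type
          cc$roi <- roi
          rows[[paste(r$session, roi)]] <- cc
        }
      }
      bind_rows(rows)
    })
    fmri_sessions <- fmri
    walltimes$fmri <- as.numeric(Sys.time() - tf, units = "secs")

    tg <- Sys.time()
    dissociation <- stage("group", {
      scopes <- list(
        all = unique(fmri$session_type),
        stable = "stable",
        changing = c("changing_up", "changing_down"),
        equiprobable = "equiprobable"
      )
      bind_rows(lapply(names(scopes), function(sc) {
        sub <- fmri %>% filter(.data$session_type %in% scopes[[sc]])
        if (nrow(sub) == 0) {
          return(NULL)
        }
        bind_rows(lapply(split(sub, sub$roi), function(d) {
          g <- combine_levels(d)
          g$roi <- d$roi[1]
          g$scope <- sc
          g
        }))
      })) %>%
        mutate(significant = .data$p < config$alpha_sig) %>%
        select(
          "roi", "contrast", "scope", "group_effect", "t", "df", "p",
          "significant", "n_subjects"
        )
    })
    walltimes$group <- as.numeric(Sys.time() - tg, units = "secs")
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rewardsurprise")),
    stages = names(walltimes),
    wall_seconds = walltimes,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(
    list(
      cohort = cohort, behavior = behavior, diagnostics = diagnostics,
      fmri_sessions = fmri_sessions, dissociation = dissociation,
      manifest = manifest
    ),
    class = "rws_pipeline"
  )
}

#' @export
print.rws_pipeline <- function(x, ...) {
  cat("<rws_pipeline> seed", x$manifest$seed, "\n")
  if (!is.null(x$behavior)) {
    cat(
      " alpha_hat =", format(x$behavior$alpha_hat, digits = 4),
      " sRE LR test: chi2 =", format(x$behavior$lrt_sre$chi2, digits = 4),
      " p =", format(x$behavior$lrt_sre$p, digits = 3), "\n"
    )
  }
  if (!is.null(x$diagnostics)) {
    cat(" shared variance (sRPE vs RRE, %):\n")
    print(as.data.frame(x$diagnostics), digits = 3)
  }
  if (!is.null(x$dissociation)) {
    cat(" significant group effects (scope = all unless RRE):\n")
    d <- x$dissociation %>% filter(.data$significant)
    print(as.data.frame(d[, c("roi", "contrast", "scope", "t", "p")]), digits = 3)
  }
  invisible(x)
}

#' Small bundled fixtures for examples and tests
#'
#' Deterministic miniature datasets: a 20-trial stable session, a 2-subject
#' mini-cohort configuration (reduced trials and sessions so the full
#' pipeline runs in seconds), and a noiseless ROI series carrying a pure
#' sRPE effect.
#'
#' @param seed Master seed.
#' @return List with `session20`, `mini_config`, `roi_noiseless` (list of
#'   `design` and `ts`).
#' @export
make_fixtures <- function(seed = 42) {
  session20 <- generate_session(
    schedule_spec("stable", n_rewarded_trials = 20),
    seed = derive_seed(seed, "fixture", "session20")
  )
  mini_config <- cohort_config(
    n_subjects = 2,
    sessions_per_type = c(
      stable = 1, changing_up = 1, changing_down = 0,
      equiprobable = 0
    ),
    n_trials = 40,
    seed = derive_seed(seed, "fixture", "mini"),
    noise_sd = 0.5
  )
  des <- build_fmri_design(session20)
  eff <- roi_effect_vector("sRPE", 0.5, 0.257)
  eff <- eff[names(eff) %in% setdiff(des$regressors, des$constant_cols)]
  ts <- simulate_roi_bold(des, eff, noise_sd = 0, seed = NULL)
  list(
    session20 = session20, mini_config = mini_config,
    roi_noiseless = list(design = des, ts = ts, effects = eff)
  )
}
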