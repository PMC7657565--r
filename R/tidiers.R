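#' Tidy a behavioural model fit
#'
#' @param x An `rws_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `se`, `z`,
#'   `p`.
#' @method tidy rws_fit
#' @export
tidy.rws_fit <- function(x, ...) {
  as_tibble(x$coefficients)
}

#' @rdname tidy.rws_fit
#' @method glance rws_fit
#' @export
glance.rws_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik, df_model = x$df_model, n_obs = x$n_obs,
    method = x$method, family = x$family, converged = x$converged
  )
}

#' Tidy a truncated-RW learning-rate fit
#'
#' @param x An `rws_rwfit` object.
#' @param ... Unused.
#' @return One-row tibble: `alpha_hat`, `scale_hat`, `residual_norm`,
#'   `flagged`.
#' @method glance rws_rwfit
#' @export
glance.rws_rwfit <- function(x, ...) {
  tibble(
    alpha_hat = x$alpha_hat, scale_hat = x$scale_hat,
    residual_norm = x$residual_norm, flagged = x$flagged
  )
}

#' Tidy a session-level GLM
#'
#' @param x An `rws_session_glm` object.
#' @param which `"contrasts"` (default) or `"betas"`.
#' @param ... Unused.
#' @return A tibble of contrast effects or per-regressor betas.
#' @method tidy rws_session_glm
#' @export
tidy.rws_session_glm <- function(x, which = c("contrasts", "betas"), ...) {
  which <- match.arg(which)
  if (which == "betas" || is.null(x$contrasts)) {
    return(as_tibble(x$betas))
  }
  as_tibble(x$contrasts)
}

#' @rdname tidy.rws_session_glm
#' @method glance rws_session_glm
#' @export
glance.rws_session_glm <- function(x, ...) {
  tibble(
    sigma = x$sigma, df_residual = x$df_residual,
    n_dropped = length(x$dropped_cols)
  )
}

#' Tidy a group-level result
#'
#' @param x An `rws_group` tibble.
#' @param ... Unused.
#' @return The group table as a plain tibble; use
#'   `attr(x, "subject_effects")` for the subject level.
#' @method tidy rws_group
#' @export
tidy.rws_group <- function(x, ...) {
  out <- x
  attr(out, "subject_effects") <- NULL
  attr(out, "method") <- NULL
  class(out) <- setdiff(class(out), "rws_group")
  as_tibble(out)
}
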