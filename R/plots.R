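#' Plot a session's reward and side structure
#'
#' Top: delivered drops per trial with the rare 2-drop events highlighted;
#' the stimulus side is shown as a rug along the bottom.
#'
#' @param object An `rws_session` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rws_session
#' @export
autoplot.rws_session <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$drops)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$drops == 2), size = 1.5) +
    ggplot2::geom_rug(
      data = df[df$side == "left", ], sides = "b",
      colour = "steelblue", alpha = 0.6
    ) +
    ggplot2::geom_rug(
      data = df[df$side == "right", ], sides = "t",
      colour = "darkorange", alpha = 0.6
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "red"),
      labels = c("1 or 3 drops", "2 drops (RRE)"), name = NULL
    ) +
    ggplot2::labs(
      x = "Rewarded trial", y = "Drops delivered",
      title = "Session reward schedule",
      subtitle = "rug: stimulus side (bottom = left, top = right)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot convolved design regressors
#'
#' @param object An `rws_fmri_design`.
#' @param regressors Which columns to draw (default: a readable subset).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rws_fmri_design
#' @export
autoplot.rws_fmri_design <- function(object,
                                     regressors = c(
                                       "reward_current", "RRE_outcome",
                                       "VS_left", "VS_right"
                                     ),
                                     ...) {
  regressors <- intersect(regressors, object$regressors)
  df <- object$design %>%
    select("time", all_of(regressors)) %>%
    tidyr::pivot_longer(-"time", names_to = "regressor", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~regressor, ncol = 1) +
    ggplot2::labs(
      x = "Time (s)", y = "z-scored regressor",
      title = "HRF-convolved session design"
    ) +
    ggplot2::theme_minimal()
}

#' Plot coefficients of a behavioural fit
#'
#' @param object An `rws_fit`.
#' @param ... Unused.
#' @return A ggplot object (point estimates with ~95% intervals).
#' @method autoplot rws_fit
#' @export
autoplot.rws_fit <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$se,
      ymax = .data$estimate + 1.96 * .data$se
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Coefficient (z-scored predictors)",
      title = paste0("Model coefficients (", object$family, ", ", object$method, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a group-level dissociation table
#'
#' Tile map of group t-statistics per ROI and contrast, faceted by session
#' scope, with significant cells outlined.
#'
#' @param dissociation The `dissociation` tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_dissociation <- function(dissociation) {
  ggplot2::ggplot(
    dissociation,
    ggplot2::aes(.data$contrast, .data$roi, fill = .data$t)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dissociation[dissociation$significant, ],
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(
      x = "Contrast", y = "ROI", fill = "group t",
      title = "Effect dissociation across synthetic ROIs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot peristimulus time courses
#'
#' @param object An `rws_timecourse` from [extract_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rws_timecourse
#' @export
autoplot.rws_timecourse <- function(object, ...) {
  ggplot2::ggplot(
    object$timecourse,
    ggplot2::aes(.data$t_rel, .data$mean_bold, colour = factor(.data$split))
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from event (s)", y = "BOLD (baselined, a.u.)",
      colour = "split",
      title = "Event-locked ROI time course (spline-upsampled)"
    ) +
    ggplot2::theme_minimal()
}
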