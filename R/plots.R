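#' Plot a natural-history trajectory
#'
#' @param object An [nh_trajectory()].
#' @param milestone Optional CDR-SB milestone to mark (default 16).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nh_trajectory
#' @export
autoplot.nh_trajectory <- function(object, milestone = 16, ...) {
  grid <- seq(object$knot_times[1], max(object$knot_times), length.out = 400)
  df <- tibble(time_years = grid, cdr_sb = nh_evaluate(object, grid))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_years, y = .data$cdr_sb)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "Years since amyloid-PET positivity",
      y = "Mean CDR-SB"
    )
  if (!is.null(milestone)) {
    p <- p + ggplot2::geom_hline(yintercept = milestone, linetype = "dashed")
  }
  p
}

#' Plot a trial's per-arm mean CDR-SB series
#'
#' @param object A [trial_summary()].
#' @param absolute Plot on the absolute CDR-SB scale (baseline added) rather
#'   than change from baseline.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_summary
#' @export
autoplot.trial_summary <- function(object, absolute = TRUE, ...) {
  df <- tidy(object)
  y <- if (absolute) "cdr_sb" else "mean_change"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$week, y = .data[[y]], colour = .data$arm
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = object$trial_name,
      x = "Week",
      y = if (absolute) "Mean CDR-SB" else "Mean CDR-SB change from baseline"
    )
}

#' Plot a scenario extrapolation against the placebo trajectory
#'
#' @param object A [scenario_trajectory()].
#' @param horizon_years Plotting horizon from treatment baseline; defaults
#'   to a little past the active arm's milestone time.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_trajectory
#' @export
autoplot.scenario_trajectory <- function(object, horizon_years = NULL, ...) {
  if (is.null(horizon_years)) horizon_years <- object$T_active * 1.1
  grid <- seq(0, horizon_years, length.out = 400)
  df <- dplyr::bind_rows(
    tibble(t = grid, cdr_sb = .placebo_score_bc(object, grid), arm = "placebo"),
    tibble(t = grid, cdr_sb = scenario_score(object, grid), arm = "active")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$cdr_sb, colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$spec$milestone_score, linetype = "dashed") +
    ggplot2::labs(
      title = paste0("Scenario: ", object$spec$kind),
      x = "Years since treatment initiation",
      y = "Mean CDR-SB"
    )
}
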