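#' Fit the mean natural-history trajectory from subject-level data
#'
#' Fits the Gaussian random-intercept model
#' \deqn{y_{ij} = f(t_{ij}) + b_i + e_{ij}, \quad b_i \sim N(0, \sigma_b^2),
#'   \; e_{ij} \sim N(0, \sigma_e^2),}
#' where \eqn{f} is a natural cubic spline of disease time with
#' `spline_df` degrees of freedom (including the intercept) and \eqn{b_i} is
#' a patient-level random intercept, by restricted maximum likelihood via
#' [lme4::lmer()]. Spline knots are placed at evenly spaced quantiles of the
#' observed times (for the default `spline_df = 5`: boundary knots at the
#' 0 and 1 quantiles, internal knots at 0.25/0.5/0.75).
#'
#' The fitted mean is tabulated on a grid of at most `grid_spacing`-year
#' spacing, monotonized (running maximum -- decreasing wiggles in the tails
#' of the basis are not interpretable as disease progression) and clipped to
#' \[0, 18\] before being returned as an [nh_trajectory()].
#'
#' @param data A data frame of longitudinal observations with columns
#'   `subject_id`, `disease_time` (years since amyloid positivity; the
#'   on-disk alias `disease_time_years` is accepted) and `cdr_sb`.
#' @param spline_df Degrees of freedom of the mean curve, intercept included.
#' @param grid_spacing Knot spacing (years) of the tabulated mean trajectory.
#' @return An object of class `trajectory_fit` with elements `trajectory`
#'   ([nh_trajectory()]), `random_intercept_sd`, `residual_sd`, and the
#'   underlying `model`.
#' @seealso [prediction_interval()], [simulate_subjects()]
#' @export
fit_mean_trajectory <- function(data, spline_df = 5, grid_spacing = 0.5) {
  stopifnot(is.data.frame(data))
  if ("disease_time_years" %in% names(data) && !"disease_time" %in% names(data)) {
    data$disease_time <- data$disease_time_years
  }
  for (col in c("subject_id", "disease_time", "cdr_sb")) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found in `data`."))
  }
  if (spline_df < 3) abort("`spline_df` must be at least 3.")
  tt <- as.numeric(data$disease_time)
  y <- as.numeric(data$cdr_sb)
  id <- factor(data$subject_id)
  if (anyNA(tt) || anyNA(y) || any(!is.finite(tt))) {
    abort("Observations must have finite, non-missing times and scores.")
  }
  n_per <- table(id)
  if (sum(n_per >= 2) < 10) {
    abort("Need at least 10 subjects with 2 or more observations each.")
  }
  if (length(unique(tt)) < 2) {
    abort("Singular design: all observations share a single disease time.")
  }

  probs <- seq(0, 1, length.out = spline_df)
  qs <- unname(quantile(tt, probs))
  if (any(diff(qs) <= 0)) {
    abort("Singular design: time quantiles are not distinct; spread of observation times is too small.")
  }
  internal <- qs[-c(1, length(qs))]
  boundary <- qs[c(1, length(qs))]

  basis <- splines::ns(tt, knots = internal, Boundary.knots = boundary)
  mf <- data.frame(.y = y, .id = id)
  mf$.B <- basis
  model <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ .B + (1 | .id), data = mf, REML = TRUE)
  ))

  vc <- as.data.frame(lme4::VarCorr(model))
  random_intercept_sd <- vc$sdcor[vc$grp == ".id"][1]
  residual_sd <- vc$sdcor[vc$grp == "Residual"][1]

  grid <- sort(unique(c(seq(boundary[1], boundary[2], by = grid_spacing), boundary[2])))
  gb <- splines::ns(grid, knots = internal, Boundary.knots = boundary)
  mean_curve <- drop(cbind(1, gb) %*% lme4::fixef(model))
  mean_curve <- pmin(18, pmax(0, cummax(mean_curve)))

  trajectory <- nh_trajectory(
    data.frame(time_years = grid, cdr_sb = mean_curve),
    interpolation = "monotone"
  )

  structure(
    list(
      trajectory = trajectory,
      random_intercept_sd = random_intercept_sd,
      residual_sd = residual_sd,
      model = model,
      spline_df = spline_df,
      knots = list(internal = internal, boundary = boundary),
      n_subjects = nlevels(id),
      n_obs = length(y)
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> df = %d natural spline mean, random intercept\n", x$spline_df
  ))
  cat(sprintf(
    "  %d subjects, %d observations; intercept SD %.3f, residual SD %.3f\n",
    x$n_subjects, x$n_obs, x$random_intercept_sd, x$residual_sd
  ))
  invisible(x)
}

#' @method tidy trajectory_fit
#' @export
tidy.trajectory_fit <- function(x, ...) {
  tidy(x$trajectory)
}

#' @method glance trajectory_fit
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    spline_df = x$spline_df,
    random_intercept_sd = x$random_intercept_sd,
    residual_sd = x$residual_sd,
    REMLcrit = lme4::REMLcrit(x$model)
  )
}

#' Patient-level prediction interval around the fitted mean
#'
#' Combines the between-subject intercept variance and the within-subject
#' residual variance into a Gaussian prediction interval
#' `mean +/- z(level) * sqrt(sigma_b^2 + sigma_e^2)`, clipped to \[0, 18\].
#' This is the band a new patient's observed CDR-SB is expected to fall in,
#' not a confidence interval for the mean curve.
#'
#' @param fit A [fit_mean_trajectory()] result.
#' @param t Disease times (years) at which to evaluate the interval.
#' @param level Coverage level, strictly between 0 and 1 (default 0.90).
#' @return A tibble with columns `time_years`, `mean`, `lower`, `upper`.
#' @export
prediction_interval <- function(fit, t, level = 0.90) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number strictly between 0 and 1.")
  }
  m <- nh_evaluate(fit$trajectory, t)
  half <- qnorm(1 - (1 - level) / 2) *
    sqrt(fit$random_intercept_sd^2 + fit$residual_sd^2)
  tibble(
    time_years = t,
    mean = m,
    lower = pmax(0, m - half),
    upper = pmin(18, m + half)
  )
}
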