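#' Trial summary trajectories
#'
#' A trial summary holds one trial's per-arm adjusted mean CDR-SB
#' change-from-baseline series on the study clock (weeks), together with the
#' mean baseline CDR-SB and the trial duration. The series are the published
#' marginal means of categorical-time models (MMRM or closely related); they
#' are consumed as inputs, never re-fit here.
#'
#' @param data A data frame with columns `arm` (`"placebo"` / `"active"`),
#'   `week` and `mean_change`. Each arm must start at week 0 with change 0,
#'   have strictly increasing visit weeks, and end at the trial duration.
#' @param trial_name Trial identifier.
#' @param baseline_mean_cdr_sb Mean baseline CDR-SB of the trial population,
#'   in \[0, 18\]. Absolute-scale series are `baseline + mean_change`.
#' @param duration_weeks Trial duration; defaults to the last visit week.
#' @param treatment Optional label for the active treatment.
#' @return An object of class `trial_summary`.
#' @export
trial_summary <- function(data, trial_name, baseline_mean_cdr_sb,
                          duration_weeks = NULL, treatment = NA_character_) {
  stopifnot(is.data.frame(data))
  for (col in c("arm", "week", "mean_change")) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found in `data`."))
  }
  if (!is.numeric(baseline_mean_cdr_sb) || length(baseline_mean_cdr_sb) != 1 ||
      baseline_mean_cdr_sb < 0 || baseline_mean_cdr_sb > 18) {
    abort("`baseline_mean_cdr_sb` must be a single CDR-SB score in [0, 18].")
  }
  arms <- as_tibble(data[c("arm", "week", "mean_change")])
  arms$arm <- as.character(arms$arm)
  if (!setequal(unique(arms$arm), c("placebo", "active"))) {
    abort('Trial data must contain exactly the arms "placebo" and "active".')
  }
  finals <- numeric(0)
  for (a in c("placebo", "active")) {
    sub <- arms[arms$arm == a, ]
    if (sub$week[1] != 0) abort(paste0("Arm `", a, "` must include the baseline visit at week 0."))
    if (any(diff(sub$week) <= 0)) abort(paste0("Visit weeks for arm `", a, "` must be strictly increasing."))
    if (abs(sub$mean_change[1]) > 1e-9) abort(paste0("Mean change at week 0 must be 0 for arm `", a, "`."))
    finals[a] <- max(sub$week)
  }
  if (is.null(duration_weeks)) duration_weeks <- unname(finals["placebo"])
  if (any(abs(finals - duration_weeks) > 1e-9)) {
    abort("Both arms must share the trial duration as their final visit week.")
  }
  arms <- dplyr::arrange(arms, .data$arm, .data$week)
  structure(
    list(
      trial_name = trial_name,
      treatment = treatment,
      duration_weeks = duration_weeks,
      baseline_mean_cdr_sb = baseline_mean_cdr_sb,
      arms = arms
    ),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf(
    "<trial_summary> %s%s: %g weeks, baseline CDR-SB %.2f, %d visits/arm\n",
    x$trial_name,
    if (is.na(x$treatment)) "" else paste0(" (", x$treatment, ")"),
    x$duration_weeks, x$baseline_mean_cdr_sb,
    sum(x$arms$arm == "placebo")
  ))
  invisible(x)
}

#' @method tidy trial_summary
#' @export
tidy.trial_summary <- function(x, ...) {
  dplyr::mutate(
    x$arms,
    trial = x$trial_name,
    cdr_sb = x$baseline_mean_cdr_sb + .data$mean_change,
    .before = 1
  )
}

#' Extract one arm's visit series
#'
#' @param trial A [trial_summary()].
#' @param arm `"placebo"` or `"active"`.
#' @return A tibble with columns `week`, `mean_change`, `cdr_sb` (absolute
#'   scale) ordered by week.
#' @export
arm_series <- function(trial, arm = c("placebo", "active")) {
  stopifnot(inherits(trial, "trial_summary"))
  arm <- match.arg(arm)
  sub <- trial$arms[trial$arms$arm == arm, c("week", "mean_change")]
  sub$cdr_sb <- trial$baseline_mean_cdr_sb + sub$mean_change
  sub
}

#' Read and write trial summary files
#'
#' JSON schema: `{"trial_name": ..., "treatment": ..., "duration_weeks": ...,
#' "baseline_mean_cdr_sb": ..., "arms": [{"arm_label": "placebo",
#' "visit_weeks": [...], "mean_change": [...]}, ...]}`. A CSV alternative
#' with columns `trial,arm,week,mean_change` is accepted when the baseline
#' and duration are supplied as arguments.
#'
#' @param path File path (`.json` or `.csv`).
#' @param baseline_mean_cdr_sb,duration_weeks Required for the CSV form.
#' @return A [trial_summary()].
#' @export
read_trial_summary <- function(path, baseline_mean_cdr_sb = NULL,
                               duration_weeks = NULL) {
  if (!file.exists(path)) abort(paste0("Trial summary file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("trial_name", "duration_weeks", "baseline_mean_cdr_sb", "arms")) {
      if (is.null(obj[[f]])) abort(paste0("Trial summary JSON missing field `", f, "`."))
    }
    arms_df <- obj$arms
    data <- purrr::map_dfr(seq_len(nrow(arms_df)), function(i) {
      tibble(
        arm = arms_df$arm_label[i],
        week = unlist(arms_df$visit_weeks[i]),
        mean_change = unlist(arms_df$mean_change[i])
      )
    })
    trial_summary(
      data,
      trial_name = obj$trial_name,
      baseline_mean_cdr_sb = obj$baseline_mean_cdr_sb,
      duration_weeks = obj$duration_weeks,
      treatment = if (is.null(obj$treatment)) NA_character_ else obj$treatment
    )
  } else {
    if (is.null(baseline_mean_cdr_sb)) {
      abort("Reading the CSV form requires `baseline_mean_cdr_sb`.")
    }
    df <- readr::read_csv(path, show_col_types = FALSE)
    trial_summary(
      df, trial_name = df$trial[1],
      baseline_mean_cdr_sb = baseline_mean_cdr_sb,
      duration_weeks = duration_weeks
    )
  }
}

#' @rdname read_trial_summary
#' @param trial A [trial_summary()] to serialize (JSON).
#' @export
write_trial_summary <- function(trial, path) {
  stopifnot(inherits(trial, "trial_summary"))
  arms <- lapply(c("placebo", "active"), function(a) {
    sub <- trial$arms[trial$arms$arm == a, ]
    list(arm_label = a, visit_weeks = sub$week, mean_change = sub$mean_change)
  })
  jsonlite::write_json(
    list(
      trial_name = trial$trial_name,
      treatment = trial$treatment,
      duration_weeks = trial$duration_weeks,
      baseline_mean_cdr_sb = trial$baseline_mean_cdr_sb,
      arms = arms
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Interpolant for a mean-change series on the study clock. Natural cubic
# spline by default; monotone fallback keeps the crossing search unique when
# the spline wiggles (the crossing time is only meaningful for a monotone
# placebo decline).
.change_interpolant <- function(week, mean_change, quiet = FALSE) {
  f <- splinefun(week, mean_change, method = "natural")
  if (!.is_nondecreasing(f, range(week), n = 1001)) {
    if (!quiet) {
      warn("Placebo mean-change spline is non-monotone; using monotone (Fritsch-Carlson) interpolation for the crossing search.")
    }
    f <- splinefun(week, mean_change, method = "monoH.FC")
  }
  f
}

#' Estimate the time delay at the final visit
#'
#' The placebo mean-change series is interpolated with a natural cubic
#' spline and the earliest study time at which the placebo curve crosses the
#' active arm's final-visit mean change is located by bisection. The time
#' delay is the trial duration minus that crossing time; the time saving is
#' the delay divided by the trial duration.
#'
#' A positive delay means the active arm is behind (less progressed than)
#' placebo. If the active arm progressed *more* than placebo at the final
#' visit, the placebo curve is extended linearly with its end slope and a
#' negative delay is returned with a warning.
#'
#' @param trial A [trial_summary()].
#' @return An object of class `treatment_effect`; see [tidy()] for the
#'   tabular form (columns `delay_at_final_weeks`, `time_saving_fraction`,
#'   `cdr_sb_difference_at_final`, `active_worse`).
#' @export
estimate_final_visit_delay <- function(trial) {
  stopifnot(inherits(trial, "trial_summary"))
  pl <- arm_series(trial, "placebo")
  ac <- arm_series(trial, "active")
  dur <- trial$duration_weeks
  f <- .change_interpolant(pl$week, pl$mean_change)
  target <- ac$mean_change[nrow(ac)]
  placebo_final <- pl$mean_change[nrow(pl)]
  active_worse <- FALSE

  if (target < -1e-9) {
    abort("Active final mean change lies below the placebo baseline; the crossing time is not defined without backward extrapolation.")
  }
  if (target > placebo_final + 1e-9) {
    active_worse <- TRUE
    slope <- f(dur, deriv = 1)
    if (slope <= 0) {
      abort("Placebo curve is flat at the final visit; cannot extrapolate a crossing for an active arm that progressed more than placebo.")
    }
    t_cross <- dur + (target - placebo_final) / slope
    warn(sprintf(
      "Active arm progressed more than placebo in %s; returning a negative delay.",
      trial$trial_name
    ))
  } else {
    lo <- 0; hi <- dur
    if (f(lo) >= target) {
      t_cross <- lo
    } else {
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        if (f(mid) >= target) hi <- mid else lo <- mid
      }
      t_cross <- hi
    }
  }

  delay <- dur - t_cross
  structure(
    list(
      trial_name = trial$trial_name,
      treatment = trial$treatment,
      duration_weeks = dur,
      delay_at_final_weeks = delay,
      time_saving_fraction = time_saving(delay, dur),
      cdr_sb_difference_at_final = target - placebo_final,
      active_worse = active_worse
    ),
    class = "treatment_effect"
  )
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf(
    "<treatment_effect> %s: delay %.1f weeks over %g weeks (time saving %d%%)\n",
    x$trial_name, x$delay_at_final_weeks, x$duration_weeks,
    round(100 * x$time_saving_fraction)
  ))
  invisible(x)
}

#' @method tidy treatment_effect
#' @export
tidy.treatment_effect <- function(x, ...) {
  tibble(
    trial = x$trial_name,
    treatment = x$treatment,
    duration_weeks = x$duration_weeks,
    delay_at_final_weeks = x$delay_at_final_weeks,
    time_saving_fraction = x$time_saving_fraction,
    cdr_sb_difference_at_final = x$cdr_sb_difference_at_final,
    active_worse = x$active_worse
  )
}

#' Time saving from a delay and a duration
#'
#' Time saving is the time delay divided by the trial (or exposure)
#' duration; it is unit-free as long as both arguments share a unit.
#'
#' @param delay,duration Durations in a common unit; `duration` must be
#'   positive.
#' @return The time-saving fraction (e.g. 0.31 for 31%).
#' @export
time_saving <- function(delay, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    abort("`duration` must be positive and finite.")
  }
  delay / duration
}

#' Anchor a trial baseline on the disease timeline
#'
#' Maps the trial population's mean baseline CDR-SB to the disease time
#' (years since amyloid-PET positivity) at which the natural-history
#' trajectory attains that score.
#'
#' @param traj An [nh_trajectory()].
#' @param baseline_mean Mean baseline CDR-SB score(s).
#' @return Years since amyloid positivity.
#' @export
anchor_baseline <- function(traj, baseline_mean) {
  nh_invert(traj, baseline_mean)
}

#' Extrapolate a trial's placebo arm with the natural history
#'
#' Post-trial placebo decline is assumed proportional to the natural-history
#' trajectory: the trajectory is shifted horizontally so that it passes
#' through the placebo arm's absolute score at the final visit. Within the
#' trial window the observed placebo series takes precedence (see
#' [scenario_trajectory()]); after the final visit the shifted trajectory
#' governs.
#'
#' @param traj An [nh_trajectory()].
#' @param trial A [trial_summary()].
#' @param anchor_time Disease time of the trial baseline; defaults to
#'   [anchor_baseline()] of the trial's baseline mean.
#' @return The shifted [nh_trajectory()], with attributes `anchor_time`,
#'   `shift` and `trial_name`.
#' @export
extrapolate_placebo <- function(traj, trial, anchor_time = NULL) {
  stopifnot(inherits(traj, "nh_trajectory"), inherits(trial, "trial_summary"))
  if (is.null(anchor_time)) {
    anchor_time <- anchor_baseline(traj, trial$baseline_mean_cdr_sb)
  }
  pl <- arm_series(trial, "placebo")
  placebo_final_abs <- pl$cdr_sb[nrow(pl)]
  t_star <- nh_invert(traj, placebo_final_abs)
  delta <- (anchor_time + weeks_to_years(trial$duration_weeks)) - t_star
  shifted <- nh_shift(traj, delta)
  attr(shifted, "anchor_time") <- anchor_time
  attr(shifted, "shift") <- delta
  attr(shifted, "trial_name") <- trial$trial_name
  shifted
}
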