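#' Scenario specification for post-trial extrapolation
#'
#' Defines how the active arm's benefit evolves after the end of the trial:
#'
#' * `enduring_delay` (conservative): the delay observed at the final visit
#'   is kept but no further benefit accrues; all later milestones occur with
#'   that fixed delay relative to the extrapolated placebo trajectory.
#' * `fading_slowing` (intermediate): the instantaneous time-saving rate
#'   decays linearly from the end-of-trial saving to 0% by the time the
#'   treated trajectory reaches the severe-dementia milestone (CDR-SB 16);
#'   the accumulated delay is kept thereafter.
#' * `continued_slowing` (optimistic): the end-of-trial time saving persists
#'   for the remaining disease course, i.e. disease time advances at a
#'   factor `1 - s` of calendar time.
#'
#' @param kind One of `"enduring_delay"`, `"fading_slowing"`,
#'   `"continued_slowing"`.
#' @param time_saving_fraction Time saving `s` at the end of the trial
#'   (delay divided by duration); `|s| < 1`. Negative values describe an
#'   active arm that progressed faster than placebo.
#' @param delay_at_final_years Delay at the final visit in years. One of
#'   `time_saving_fraction` / `delay_at_final_years` may be omitted and is
#'   filled in from the other via `d_end = s * T_end`; if both are supplied
#'   they must agree to 1e-9.
#' @param trial_end_years Trial duration `T_end` on the from-baseline clock,
#'   in years (0 for hypothetical interventions with no trial window).
#' @param fade_mode For `fading_slowing`: `"treated_time"` (default; rate
#'   linear in time on treatment) or `"cdr_stage"` (rate linear in the
#'   current CDR-SB score's distance from the milestone).
#' @param fade_horizon_years For `fading_slowing`: fix the time (from
#'   baseline) at which the rate reaches 0. Default `NULL` solves it
#'   self-consistently as the time the treated trajectory reaches the
#'   milestone.
#' @param milestone_score CDR-SB milestone; 16 (severe dementia).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("enduring_delay", "fading_slowing", "continued_slowing"),
                          time_saving_fraction = NULL,
                          delay_at_final_years = NULL,
                          trial_end_years = 0,
                          fade_mode = c("treated_time", "cdr_stage"),
                          fade_horizon_years = NULL,
                          milestone_score = 16) {
  kind <- match.arg(kind)
  fade_mode <- match.arg(fade_mode)
  if (!is.numeric(trial_end_years) || trial_end_years < 0) {
    abort("`trial_end_years` must be a non-negative duration in years.")
  }
  if (is.null(time_saving_fraction) && is.null(delay_at_final_years)) {
    abort("Supply `time_saving_fraction` and/or `delay_at_final_years`.")
  }
  if (is.null(time_saving_fraction)) {
    if (trial_end_years == 0) {
      if (abs(delay_at_final_years) > 1e-12) {
        abort("With `trial_end_years = 0`, the delay at final must be 0; supply `time_saving_fraction` instead.")
      }
      abort("With `trial_end_years = 0`, supply `time_saving_fraction`.")
    }
    time_saving_fraction <- delay_at_final_years / trial_end_years
  }
  if (is.null(delay_at_final_years)) {
    delay_at_final_years <- time_saving_fraction * trial_end_years
  }
  if (abs(time_saving_fraction) >= 1) {
    abort("`time_saving_fraction` must satisfy |s| < 1 (s = 1 never progresses).")
  }
  if (abs(delay_at_final_years - time_saving_fraction * trial_end_years) > 1e-9) {
    abort("`delay_at_final_years` and `time_saving_fraction * trial_end_years` disagree (tolerance 1e-9).")
  }
  if (!is.null(fade_horizon_years) && fade_horizon_years <= trial_end_years) {
    abort("`fade_horizon_years` must lie after the end of the trial.")
  }
  structure(
    list(
      kind = kind,
      s = time_saving_fraction,
      d_end = delay_at_final_years,
      T_end = trial_end_years,
      fade_mode = fade_mode,
      fade_horizon = fade_horizon_years,
      milestone_score = milestone_score
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: s = %.3f, delay at final %.3f y, trial end %.3f y\n",
    x$kind, x$s, x$d_end, x$T_end
  ))
  invisible(x)
}

# Crossing of a monotone mean-change interpolant with a target change; weeks.
# Beyond-final targets are reached by linear continuation with the end slope.
.cross_week <- function(f, dur, target) {
  final <- f(dur)
  if (target > final + 1e-12) {
    slope <- f(dur, deriv = 1)
    if (slope <= 0) abort("Placebo curve is flat at the final visit; crossing undefined.")
    return(dur + (target - final) / slope)
  }
  if (f(0) >= target) return(0)
  lo <- 0; hi <- dur
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Extrapolated active-arm trajectory under a scenario
#'
#' Combines the extrapolated placebo trajectory (see
#' [extrapolate_placebo()]), the scenario rule and, when available, the
#' observed trial series into a queryable object: `cumulative_delay()` gives
#' the treatment-associated delay at any time from treatment baseline and
#' `scenario_score()` the projected mean CDR-SB of the treated arm.
#'
#' Within the trial window the observed series take precedence (the delay at
#' study time `t` is computed from the crossing of the placebo series with
#' the active arm's mean change at `t`, the same construction as
#' [estimate_final_visit_delay()]); the scenario rule applies past the final
#' visit. All three rules agree with the observed delay `d_end` at the end
#' of the trial.
#'
#' @param placebo_traj An [nh_trajectory()] describing the (extrapolated)
#'   placebo course on the disease timeline.
#' @param spec A [scenario_spec()].
#' @param anchor_time Disease time (years since amyloid positivity) of the
#'   treatment baseline. Defaults to the `anchor_time` attribute attached by
#'   [extrapolate_placebo()], if present.
#' @param trial Optional [trial_summary()] providing the observed in-trial
#'   series.
#' @return An object of class `scenario_trajectory`.
#' @export
scenario_trajectory <- function(placebo_traj, spec, anchor_time = NULL, trial = NULL) {
  stopifnot(inherits(placebo_traj, "nh_trajectory"), inherits(spec, "scenario_spec"))
  if (is.null(anchor_time)) anchor_time <- attr(placebo_traj, "anchor_time")
  if (is.null(anchor_time)) abort("`anchor_time` is required (years since amyloid positivity at baseline).")
  if (!is.null(trial)) {
    stopifnot(inherits(trial, "trial_summary"))
    if (abs(weeks_to_years(trial$duration_weeks) - spec$T_end) > 1e-6) {
      abort("`spec$trial_end_years` must equal the trial duration.")
    }
  }

  milestone <- spec$milestone_score
  T_p <- nh_invert(placebo_traj, milestone) - anchor_time
  if (T_p <= 0) abort("The placebo trajectory has already reached the milestone at baseline.")

  st <- structure(
    list(
      spec = spec, placebo_traj = placebo_traj, anchor_time = anchor_time,
      trial = trial, T_p = T_p, T_active = NA_real_, fade_T16 = NULL,
      fade_grid = NULL
    ),
    class = "scenario_trajectory"
  )

  if (spec$kind == "fading_slowing") {
    if (T_p <= spec$T_end) {
      abort("Milestone is reached within the trial window; the fading rule has no room to act.")
    }
    if (spec$fade_mode == "cdr_stage") {
      st <- .fade_stage_precompute(st)
    } else {
      st$fade_T16 <- if (!is.null(spec$fade_horizon)) {
        spec$fade_horizon
      } else {
        .fade_fixed_point(st)
      }
    }
  }

  st$T_active <- .active_milestone_time(st)
  st
}

#' @export
print.scenario_trajectory <- function(x, ...) {
  cat(sprintf(
    "<scenario_trajectory> %s (s = %.3f): placebo reaches CDR-SB %g at %.2f y, active at %.2f y (delay %.2f y)\n",
    x$spec$kind, x$spec$s, x$spec$milestone_score, x$T_p, x$T_active,
    x$T_active - x$T_p
  ))
  invisible(x)
}

# Self-consistent fade horizon: the linear-in-treated-time fade ends when the
# treated trajectory reaches the milestone, which itself depends on the fade.
# Damped fixed-point iteration on T16 = T_p + d_end + s (T16 - T_end) / 2,
# seeded with the continued-slowing milestone time.
.fade_fixed_point <- function(st) {
  spec <- st$spec
  T16 <- st$T_p / (1 - spec$s)
  for (i in seq_len(200)) {
    g <- st$T_p + spec$d_end + spec$s * (T16 - spec$T_end) / 2
    T16_new <- T16 + 0.5 * (g - T16)
    if (abs(T16_new - T16) < 1e-6) {
      T16 <- T16_new
      if (T16 <= spec$T_end) {
        abort("Fading fade horizon collapsed into the trial window; scenario is degenerate.")
      }
      return(T16)
    }
    T16 <- T16_new
  }
  abort("Fading-scenario fixed point did not converge in 200 iterations (tol 1e-6 years).")
}

# cdr_stage fade: the instantaneous saving rate is proportional to the
# treated arm's remaining CDR-SB distance to the milestone, r(u) =
# s * (M - C(u)) / (M - C_end). Coupled with C(u) = P(u - D(u)) this is an
# ODE in the cumulative delay D, integrated with fixed-step RK4.
.fade_stage_precompute <- function(st, step = 0.005) {
  spec <- st$spec
  M <- spec$milestone_score
  P <- .placebo_score_fun(st)
  # treated arm's score at the end of the trial sets the fade normalization
  C_end <- if (!is.null(st$trial)) {
    ac <- arm_series(st$trial, "active")
    st$trial$baseline_mean_cdr_sb + ac$mean_change[nrow(ac)]
  } else {
    P(spec$T_end - spec$d_end)
  }
  if (C_end >= M - 1e-9) {
    st$fade_grid <- list(u = spec$T_end, D = spec$d_end, T_active = spec$T_end)
    return(st)
  }
  denom <- M - C_end
  rate <- function(u, D) {
    C <- P(u - D)
    spec$s * max(0, (M - C)) / denom
  }
  u_max <- (.nh_window(st$placebo_traj)[2] - st$anchor_time)
  n_max <- ceiling((u_max - spec$T_end) / step)
  u <- spec$T_end; D <- spec$d_end
  us <- numeric(n_max + 1); Ds <- numeric(n_max + 1)
  us[1] <- u; Ds[1] <- D
  T_active <- NA_real_
  i <- 1
  while (i <= n_max) {
    k1 <- rate(u, D)
    k2 <- rate(u + step / 2, D + step * k1 / 2)
    k3 <- rate(u + step / 2, D + step * k2 / 2)
    k4 <- rate(u + step, D + step * k3)
    D <- D + step * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    u <- u + step
    i <- i + 1
    us[i] <- u; Ds[i] <- D
    if (P(u - D) >= M) { T_active <- u; break }
  }
  st$fade_grid <- list(u = us[seq_len(i)], D = Ds[seq_len(i)], T_active = T_active)
  st
}

# Placebo mean score on the from-baseline clock; the observed placebo series
# takes precedence inside the trial window.
.placebo_score_fun <- function(st) {
  trial <- st$trial
  if (is.null(trial)) {
    return(function(u) nh_evaluate(st$placebo_traj, st$anchor_time + u))
  }
  dur_y <- weeks_to_years(trial$duration_weeks)
  pl <- arm_series(trial, "placebo")
  f <- .change_interpolant(pl$week, pl$mean_change, quiet = TRUE)
  function(u) {
    inwin <- u >= 0 & u <= dur_y + 1e-12
    out <- numeric(length(u))
    if (any(inwin)) {
      out[inwin] <- trial$baseline_mean_cdr_sb + f(years_to_weeks(u[inwin]))
    }
    if (any(!inwin)) {
      out[!inwin] <- nh_evaluate(st$placebo_traj, st$anchor_time + u[!inwin])
    }
    out
  }
}

.placebo_score_bc <- function(st, u) .placebo_score_fun(st)(u)

# Rule-based cumulative delay for t >= T_end (years, vectorized).
.delay_rule <- function(st, t) {
  spec <- st$spec
  switch(spec$kind,
    enduring_delay = rep(spec$d_end, length(t)),
    continued_slowing = spec$s * t,
    fading_slowing = {
      if (spec$fade_mode == "cdr_stage") {
        g <- st$fade_grid
        approx_fun <- stats::approxfun(g$u, g$D, rule = 2)
        approx_fun(t)
      } else {
        T16 <- st$fade_T16
        tt <- pmin(t, T16)
        spec$d_end + spec$s * (tt - spec$T_end) *
          (T16 - (tt + spec$T_end) / 2) / (T16 - spec$T_end)
      }
    }
  )
}

#' Cumulative treatment-associated delay
#'
#' The delay, at time `t` from treatment baseline, between the treated
#' trajectory and the extrapolated placebo trajectory: the treated arm's
#' disease state at `t` is the one placebo had at `t - cumulative_delay(t)`.
#'
#' @param st A [scenario_trajectory()].
#' @param t Times from treatment baseline, in years (non-negative).
#' @return Numeric vector of delays in years.
#' @export
cumulative_delay <- function(st, t) {
  stopifnot(inherits(st, "scenario_trajectory"))
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative times (years) from treatment baseline.")
  }
  spec <- st$spec
  out <- numeric(length(t))
  inwin <- t < spec$T_end - 1e-12
  if (any(inwin)) {
    if (!is.null(st$trial)) {
      pl <- arm_series(st$trial, "placebo")
      ac <- arm_series(st$trial, "active")
      f <- .change_interpolant(pl$week, pl$mean_change, quiet = TRUE)
      g <- .change_interpolant(ac$week, ac$mean_change, quiet = TRUE)
      out[inwin] <- vapply(t[inwin], function(ti) {
        w <- years_to_weeks(ti)
        weeks_to_years(w - .cross_week(f, st$trial$duration_weeks, g(w)))
      }, numeric(1))
    } else {
      # no observed series: ramp at the trial-average saving rate
      out[inwin] <- spec$s * t[inwin]
    }
  }
  if (any(!inwin)) out[!inwin] <- .delay_rule(st, t[!inwin])
  out
}

#' Projected mean CDR-SB of the treated arm
#'
#' @inheritParams cumulative_delay
#' @return Numeric vector of mean CDR-SB scores.
#' @export
scenario_score <- function(st, t) {
  stopifnot(inherits(st, "scenario_trajectory"))
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative times (years) from treatment baseline.")
  }
  spec <- st$spec
  out <- numeric(length(t))
  inwin <- t <= weeks_to_years(if (!is.null(st$trial)) st$trial$duration_weeks else years_to_weeks(spec$T_end)) + 1e-12
  if (!is.null(st$trial) && any(inwin)) {
    ac <- arm_series(st$trial, "active")
    g <- .change_interpolant(ac$week, ac$mean_change, quiet = TRUE)
    out[inwin] <- st$trial$baseline_mean_cdr_sb + g(years_to_weeks(t[inwin]))
  } else if (any(inwin)) {
    d <- cumulative_delay(st, t[inwin])
    out[inwin] <- .placebo_score_bc(st, t[inwin] - d)
  }
  if (any(!inwin)) {
    d <- cumulative_delay(st, t[!inwin])
    out[!inwin] <- .placebo_score_bc(st, t[!inwin] - d)
  }
  out
}

# Time (from baseline) at which the treated arm reaches the milestone:
# root of t - D(t) = T_p. t - D(t) is increasing because the saving rate is
# bounded by |s| < 1.
.active_milestone_time <- function(st) {
  spec <- st$spec
  switch(spec$kind,
    enduring_delay = st$T_p + spec$d_end,
    continued_slowing = st$T_p / (1 - spec$s),
    fading_slowing = {
      if (spec$fade_mode == "cdr_stage" && !is.na(st$fade_grid$T_active) &&
          !is.null(st$fade_grid$T_active)) {
        g <- st$fade_grid
        if (!is.na(g$T_active)) return(g$T_active)
      }
      lo <- spec$T_end
      hi <- (st$T_p + abs(spec$d_end) + 1) / (1 - abs(spec$s)) + 5
      obj <- function(t) t - .delay_rule(st, t) - st$T_p
      if (obj(lo) > 0) return(lo)
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        if (obj(mid) >= 0) hi <- mid else lo <- mid
      }
      hi
    }
  )
}

#' Milestone delay with uncertainty bracket
#'
#' Per-arm years from treatment baseline to the severe-dementia milestone
#' (CDR-SB 16) and the treatment-associated delay, with an uncertainty
#' bracket obtained by re-running the scenario with the time-saving fraction
#' decreased and increased by `delta` (default 10 percentage points; for the
#' enduring scenario the final-visit delay is rescaled to
#' `(s -/+ delta) * T_end`).
#'
#' @param placebo_traj The extrapolated placebo [nh_trajectory()].
#' @param st A [scenario_trajectory()] built on `placebo_traj`.
#' @param milestone CDR-SB milestone (must match the scenario spec).
#' @param delta Half-width of the time-saving bracket (fraction); `NULL`
#'   suppresses the bracket.
#' @return A one-row tibble with columns `scenario`, `time_saving_fraction`,
#'   `placebo_years`, `active_years`, `delay_years`, `delay_lower`,
#'   `delay_upper`.
#' @export
delay_to_severe_dementia <- function(placebo_traj, st, milestone = 16, delta = 0.10) {
  stopifnot(inherits(st, "scenario_trajectory"))
  if (milestone != st$spec$milestone_score) {
    abort("`milestone` must match the scenario spec's milestone score.")
  }
  delay <- st$T_active - st$T_p
  lower <- upper <- NA_real_
  if (!is.null(delta) && delta > 0) {
    band <- uncertainty_band(
      function(s_new) {
        st2 <- .rebuild_with_s(st, s_new)
        st2$T_active - st2$T_p
      },
      s = st$spec$s, delta = delta
    )
    lower <- band$lower
    upper <- band$upper
  } else if (!is.null(delta)) {
    lower <- upper <- delay
  }
  tibble(
    scenario = st$spec$kind,
    time_saving_fraction = st$spec$s,
    placebo_years = st$T_p,
    active_years = st$T_active,
    delay_years = delay,
    delay_lower = lower,
    delay_upper = upper
  )
}

.rebuild_with_s <- function(st, s_new) {
  spec <- st$spec
  new_spec <- scenario_spec(
    kind = spec$kind,
    time_saving_fraction = s_new,
    trial_end_years = spec$T_end,
    fade_mode = spec$fade_mode,
    fade_horizon_years = spec$fade_horizon,
    milestone_score = spec$milestone_score
  )
  scenario_trajectory(st$placebo_traj, new_spec, st$anchor_time, st$trial)
}

#' Re-run a scenario computation at bracketing time-saving fractions
#'
#' Addresses the uncertainty of the extracted time-saving estimate by
#' recomputing a quantity at `s - delta` and `s + delta`; with
#' `delta = 0.10` this approximately brackets a 95% confidence interval
#' under the reported precision of patient-level time-saving estimates.
#'
#' @param f A function of the time-saving fraction returning a scalar.
#' @param s Point estimate of the time-saving fraction.
#' @param delta Half-width in absolute percentage points (fraction).
#' @return A one-row tibble with columns `lower` and `upper` (sorted).
#' @export
uncertainty_band <- function(f, s, delta = 0.10) {
  if (!is.numeric(delta) || delta < 0) abort("`delta` must be non-negative.")
  if (s - delta <= -1 || s + delta >= 1) {
    abort("`s` plus/minus `delta` must stay inside (-1, 1).")
  }
  vals <- sort(c(f(s - delta), f(s + delta)))
  tibble(lower = vals[1], upper = vals[2])
}

#' Hypothetical interventions at arbitrary disease stages
#'
#' Projects the delay in reaching the severe-dementia milestone for an
#' intervention starting at a given disease time with time-saving fraction
#' `s`, applied from the start (no trial window). Under continued slowing
#' the delay is `(T16 - start) * s / (1 - s)`, computed here from the
#' trajectory; under fading slowing the rate decays linearly to 0 at the
#' (self-consistent) milestone time.
#'
#' @param traj An [nh_trajectory()] (natural history).
#' @param start_time Disease times (years since amyloid positivity) at which
#'   the intervention starts; vectorized.
#' @param s Time-saving fraction of the intervention.
#' @param kind `"continued_slowing"` or `"fading_slowing"`.
#' @param milestone CDR-SB milestone (default 16).
#' @param fade_mode See [scenario_spec()].
#' @return A tibble with one row per `start_time`: `start_time`, `kind`,
#'   `time_saving_fraction`, `placebo_years`, `active_years`, `delay_years`
#'   (all times in years; `placebo_years`/`active_years` are measured from
#'   the intervention start).
#' @export
hypothetical_intervention <- function(traj, start_time, s,
                                      kind = c("continued_slowing", "fading_slowing"),
                                      milestone = 16,
                                      fade_mode = c("treated_time", "cdr_stage")) {
  stopifnot(inherits(traj, "nh_trajectory"))
  kind <- match.arg(kind)
  fade_mode <- match.arg(fade_mode)
  purrr::map_dfr(start_time, function(u0) {
    if (nh_evaluate(traj, u0) >= milestone) {
      abort(sprintf(
        "Intervention start %.2f y is at or past the milestone score %g.", u0, milestone
      ))
    }
    spec <- scenario_spec(
      kind = kind, time_saving_fraction = s, trial_end_years = 0,
      fade_mode = fade_mode, milestone_score = milestone
    )
    st <- scenario_trajectory(traj, spec, anchor_time = u0)
    dplyr::mutate(
      delay_to_severe_dementia(traj, st, milestone = milestone, delta = NULL),
      start_time = u0, .before = 1
    )
  })
}

#' Projected differences from placebo at fixed horizons
#'
#' Score difference from placebo and cumulative delay of the treated arm at
#' given horizons after treatment initiation (3, 4 and 5 years by default).
#'
#' @param placebo_traj The extrapolated placebo [nh_trajectory()].
#' @param st A [scenario_trajectory()].
#' @param horizons Horizons in years from treatment baseline (at or after
#'   the end of the trial for the scenario rules to apply).
#' @return A tibble with columns `horizon_years`, `placebo_score`,
#'   `active_score`, `cdr_sb_difference` (active minus placebo; negative
#'   favours treatment) and `delay_years`.
#' @export
projected_difference_at <- function(placebo_traj, st, horizons = c(3, 4, 5)) {
  stopifnot(inherits(st, "scenario_trajectory"))
  if (any(horizons < 0)) abort("Horizons must be at or after the treatment baseline.")
  placebo <- .placebo_score_bc(st, horizons)
  active <- scenario_score(st, horizons)
  tibble(
    horizon_years = horizons,
    placebo_score = placebo,
    active_score = active,
    cdr_sb_difference = active - placebo,
    delay_years = cumulative_delay(st, horizons)
  )
}
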