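#' Anchor trials on the disease timeline
#'
#' For each trial, maps the mean baseline CDR-SB to the predicted time since
#' amyloid-PET positivity on the natural-history trajectory.
#'
#' @param trials A list of [trial_summary()] objects.
#' @param traj An [nh_trajectory()].
#' @return A tibble with columns `trial`, `treatment`,
#'   `baseline_mean_cdr_sb`, `anchor_years` (full precision; see
#'   [round_report()] for rendering).
#' @export
anchor_table <- function(trials, traj) {
  if (inherits(trials, "trial_summary")) trials <- list(trials)
  purrr::map_dfr(trials, function(tr) {
    tibble(
      trial = tr$trial_name,
      treatment = tr$treatment,
      baseline_mean_cdr_sb = tr$baseline_mean_cdr_sb,
      anchor_years = anchor_baseline(traj, tr$baseline_mean_cdr_sb)
    )
  })
}

.scenario_kinds <- c("enduring_delay", "fading_slowing", "continued_slowing")

# Build the three scenario trajectories for one trial from its estimated
# final-visit effect.
.trial_scenarios <- function(traj, trial, milestone = 16) {
  eff <- estimate_final_visit_delay(trial)
  anchor <- anchor_baseline(traj, trial$baseline_mean_cdr_sb)
  placebo <- extrapolate_placebo(traj, trial, anchor)
  specs <- lapply(.scenario_kinds, function(k) {
    scenario_spec(
      kind = k,
      time_saving_fraction = eff$time_saving_fraction,
      trial_end_years = weeks_to_years(trial$duration_weeks),
      milestone_score = milestone
    )
  })
  list(
    effect = eff, anchor = anchor, placebo = placebo,
    scenarios = lapply(specs, function(sp) scenario_trajectory(placebo, sp, anchor, trial))
  )
}

#' Milestone-delay table across trials and scenarios
#'
#' For each trial: estimates the final-visit delay from the summary series,
#' anchors the trial on the natural-history trajectory, extrapolates the
#' placebo arm, runs the three scenarios and computes per-scenario delays in
#' reaching the severe-dementia milestone with uncertainty brackets
#' (time-saving fraction -/+ `delta`).
#'
#' @param trials A list of [trial_summary()] objects (or a single one).
#' @param traj An [nh_trajectory()].
#' @param milestone CDR-SB milestone score (default 16).
#' @param delta Bracket half-width on the time-saving fraction.
#' @return A tibble with one row per trial and columns `placebo_years` plus
#'   `<scenario>`, `<scenario>_lower`, `<scenario>_upper` for `enduring`,
#'   `fading` and `continued`. Full precision; render with [round_report()].
#' @export
milestone_table <- function(trials, traj, milestone = 16, delta = 0.10) {
  if (inherits(trials, "trial_summary")) trials <- list(trials)
  purrr::map_dfr(trials, function(tr) {
    parts <- .trial_scenarios(traj, tr, milestone)
    res <- purrr::map_dfr(parts$scenarios, function(st) {
      delay_to_severe_dementia(parts$placebo, st, milestone, delta)
    })
    short <- c(enduring_delay = "enduring", fading_slowing = "fading",
               continued_slowing = "continued")
    out <- tibble(
      trial = tr$trial_name,
      treatment = tr$treatment,
      time_saving_fraction = parts$effect$time_saving_fraction,
      placebo_years = res$placebo_years[1]
    )
    for (i in seq_len(nrow(res))) {
      nm <- short[[res$scenario[i]]]
      out[[nm]] <- res$delay_years[i]
      out[[paste0(nm, "_lower")]] <- res$delay_lower[i]
      out[[paste0(nm, "_upper")]] <- res$delay_upper[i]
    }
    out
  })
}

#' Projected differences at fixed horizons across scenarios
#'
#' @param trial A [trial_summary()].
#' @param traj An [nh_trajectory()].
#' @param horizons Years after treatment initiation (default 3, 4, 5).
#' @param milestone CDR-SB milestone score.
#' @return A tibble with one row per scenario and horizon: projected CDR-SB
#'   difference from placebo and cumulative delay.
#' @export
horizon_table <- function(trial, traj, horizons = c(3, 4, 5), milestone = 16) {
  stopifnot(inherits(trial, "trial_summary"))
  parts <- .trial_scenarios(traj, trial, milestone)
  purrr::map_dfr(parts$scenarios, function(st) {
    dplyr::mutate(
      projected_difference_at(parts$placebo, st, horizons),
      trial = trial$trial_name,
      scenario = st$spec$kind,
      .before = 1
    )
  })
}

#' Apply the reporting rounding conventions
#'
#' Rounds columns by name suffix, matching the precision of the published
#' tables: `*_years`/`*years*` to 1 decimal, `*_weeks` to 1 decimal,
#' `*_pct` to integers, and scenario delay columns (`enduring`, `fading`,
#' `continued` and their brackets) to 1 decimal. Raw tables carry full
#' precision; rounding is a rendering step only.
#'
#' @param x A tibble produced by one of the table functions.
#' @return The tibble with rounded numeric columns.
#' @export
round_report <- function(x) {
  one_dec <- grepl("(years|weeks|^enduring|^fading|^continued)", names(x))
  ints <- grepl("_pct$", names(x))
  for (i in which(one_dec & vapply(x, is.numeric, logical(1)))) {
    x[[i]] <- round(x[[i]], 1)
  }
  for (i in which(ints & vapply(x, is.numeric, logical(1)))) {
    x[[i]] <- round(x[[i]])
  }
  x
}
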