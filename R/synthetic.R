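#' Calibration anchors for the synthetic natural-history trajectory
#'
#' The long-term CDR-SB trajectory used as a reference in this package is a
#' synthetic stand-in constrained to pass through published anchor points on
#' the disease timeline: the trial baselines (2.49 CDR-SB at 10.0 years
#' since amyloid positivity, 3.22 at 10.7, 3.68 at 11.1), the
#' severe-dementia milestone (16 at 17.7 years) and the boundary anchors
#' (0 at positivity, scale maximum 18 at 21 years).
#'
#' @return A tibble with columns `time_years` and `cdr_sb`.
#' @export
default_anchor_points <- function() {
  tibble(
    time_years = c(0, 10.0, 10.7, 11.1, 17.7, 21.0),
    cdr_sb = c(0, 2.49, 3.22, 3.68, 16.0, 18.0)
  )
}

#' Generate the calibrated synthetic natural-history trajectory
#'
#' Interpolates the anchor points with a monotone cubic (Fritsch-Carlson)
#' spline -- which passes through the anchors exactly and guarantees an
#' invertible curve -- and tabulates it on a dense knot grid
#' (`grid_spacing` of at most 0.5 years). The local shape between anchors
#' is not identified by the published values; the monotone interpolant is a
#' neutral choice.
#'
#' @param anchors Data frame of anchor points (`time_years`, `cdr_sb`),
#'   monotone and within \[0, 18\].
#' @param grid_spacing Knot spacing of the tabulated trajectory, years.
#' @return An [nh_trajectory()] passing through every anchor to within
#'   0.01 CDR-SB points (exactly, by construction).
#' @export
generate_fixture_trajectory <- function(anchors = default_anchor_points(),
                                        grid_spacing = 0.25) {
  stopifnot(is.data.frame(anchors))
  t <- anchors$time_years
  s <- anchors$cdr_sb
  if (any(diff(t) <= 0) || any(diff(s) < 0)) {
    abort("Anchor points must be strictly increasing in time and non-decreasing in score.")
  }
  if (any(s < 0 | s > 18)) abort("Anchor scores must lie in [0, 18].")
  if (grid_spacing > 0.5) abort("`grid_spacing` must be at most 0.5 years.")
  f <- splinefun(t, s, method = "monoH.FC")
  grid <- sort(unique(c(seq(min(t), max(t), by = grid_spacing), t)))
  traj <- nh_trajectory(
    data.frame(time_years = grid, cdr_sb = pmin(18, pmax(0, f(grid)))),
    interpolation = "monotone"
  )
  miss <- abs(nh_evaluate(traj, t) - s)
  if (any(miss > 0.01)) {
    abort("Generated trajectory misses an anchor by more than 0.01 CDR-SB points.")
  }
  traj
}

#' Simulate subject-level longitudinal CDR-SB records
#'
#' Emulates the structure of a longitudinal cohort staged on the disease
#' timeline: per-subject observation times uniform in `time_window`, scores
#' equal to the trajectory mean plus a subject-level random intercept
#' (SD `intercept_sd`) plus residual noise (SD `residual_sd`), rounded to
#' the half-point CDR-SB grid and clipped to \[0, 18\].
#'
#' @param traj An [nh_trajectory()].
#' @param n_subjects,visits_per_subject Cohort dimensions.
#' @param intercept_sd,residual_sd Standard deviations of the random
#'   intercept and residual (CDR-SB points); non-negative.
#' @param time_window Range of observation times, years since amyloid
#'   positivity. The default (6, 18) spans late-preclinical to severe
#'   dementia while avoiding the floor region where CDR-SB carries little
#'   signal.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return A tibble with columns `subject_id`, `disease_time`, `cdr_sb`.
#' @export
simulate_subjects <- function(traj, n_subjects = 500, visits_per_subject = 4,
                              intercept_sd = 1.0, residual_sd = 0.5,
                              time_window = c(6, 18), seed = 1) {
  stopifnot(inherits(traj, "nh_trajectory"))
  if (n_subjects < 1 || visits_per_subject < 1) abort("Cohort dimensions must be at least 1.")
  if (intercept_sd < 0 || residual_sd < 0) abort("Standard deviations must be non-negative.")
  if (diff(time_window) <= 0) abort("`time_window` must be a non-empty time range.")
  n_obs <- n_subjects * visits_per_subject
  withr::with_seed(seed, {
    times <- runif(n_obs, time_window[1], time_window[2])
    id <- rep(seq_len(n_subjects), each = visits_per_subject)
    b <- rnorm(n_subjects, 0, intercept_sd)[id]
    e <- rnorm(n_obs, 0, residual_sd)
    raw <- nh_evaluate(traj, times) + b + e
    tibble(
      subject_id = id,
      disease_time = times,
      cdr_sb = pmin(18, pmax(0, round(raw * 2) / 2))
    )
  })
}

#' Simulate a trial summary with a known ground-truth effect
#'
#' The placebo arm follows the natural-history trajectory from the anchor
#' time (`mean_change(t) = traj(anchor + t) - traj(anchor)`); the active arm
#' progresses along the same trajectory at a slower pace (continued slowing
#' at fraction `s` during the trial:
#' `traj(anchor + (1 - s) t) - traj(anchor)`), so the true delay at the
#' final visit is exactly `s * duration`. Optional Gaussian noise on the
#' post-baseline means emulates MMRM sampling error.
#'
#' @param traj An [nh_trajectory()].
#' @param anchor_time Disease time of the trial baseline, years.
#' @param visit_weeks Visit schedule on the study clock, starting at 0.
#' @param s True time-saving fraction.
#' @param mean_noise_sd SD of noise added to each post-baseline mean
#'   (CDR-SB points; 0 for noiseless estimator tests, ~0.1 emulates MMRM
#'   standard errors).
#' @param seed Integer seed (used only when `mean_noise_sd > 0`).
#' @param trial_name,treatment Labels for the simulated trial.
#' @return A [trial_summary()].
#' @export
simulate_trial <- function(traj, anchor_time, visit_weeks, s,
                           mean_noise_sd = 0, seed = 1,
                           trial_name = "simulated", treatment = NA_character_) {
  stopifnot(inherits(traj, "nh_trajectory"))
  if (visit_weeks[1] != 0) abort("`visit_weeks` must start at 0 (baseline).")
  if (abs(s) >= 1) abort("|s| must be below 1.")
  t_y <- weeks_to_years(visit_weeks)
  baseline <- nh_evaluate(traj, anchor_time)
  placebo <- nh_evaluate(traj, anchor_time + t_y) - baseline
  active <- nh_evaluate(traj, anchor_time + (1 - s) * t_y) - baseline
  if (mean_noise_sd > 0) {
    withr::with_seed(seed, {
      k <- length(visit_weeks) - 1
      placebo[-1] <- placebo[-1] + rnorm(k, 0, mean_noise_sd)
      active[-1] <- active[-1] + rnorm(k, 0, mean_noise_sd)
    })
  }
  data <- tibble(
    arm = rep(c("placebo", "active"), each = length(visit_weeks)),
    week = rep(visit_weeks, 2),
    mean_change = c(placebo, active)
  )
  trial_summary(
    data, trial_name = trial_name,
    baseline_mean_cdr_sb = baseline,
    duration_weeks = max(visit_weeks),
    treatment = treatment
  )
}

#' Published trial-level inputs
#'
#' Trial duration, mean baseline CDR-SB, final-visit CDR-SB difference,
#' estimated final-visit time delay and time saving for the three positive
#' phase 3 trials of high-clearance amyloid-targeting antibodies. These
#' published summary values are the inputs from which the packaged
#' synthetic fixtures are built.
#'
#' @return A tibble with one row per trial.
#' @export
published_trials <- function() {
  tibble(
    trial = c("EMERGE", "CLARITY AD", "TRAILBLAZER-ALZ 2"),
    treatment = c("Aducanumab", "Lecanemab", "Donanemab"),
    duration_weeks = c(78, 79, 76),
    baseline_mean_cdr_sb = c(2.49, 3.22, 3.68),
    cdr_sb_difference_at_final = c(-0.39, -0.45, -0.67),
    delay_at_final_weeks = c(15.7, 24.3, 30.1),
    time_saving_pct = c(20, 31, 40)
  )
}

.fixture_visit_schedules <- function() {
  list(
    "EMERGE" = seq(0, 78, by = 13),
    "CLARITY AD" = c(0, 13, 26, 39, 52, 65, 79),
    "TRAILBLAZER-ALZ 2" = c(0, 12, 24, 36, 52, 64, 76)
  )
}

#' Build the synthetic fixture for one published trial
#'
#' Intermediate visit means for the published trials are only available as
#' digitized graph extractions, which are not reproduced here. The packaged
#' fixtures instead generate both arms from the synthetic natural-history
#' trajectory with [simulate_trial()], calibrated so that the final-visit
#' time delay equals the published estimate (the published baseline,
#' duration and delay are preserved; the final-visit CDR-SB difference is
#' approximate).
#'
#' @param traj An [nh_trajectory()]; defaults to the calibrated synthetic
#'   trajectory.
#' @param trial Trial name, one of `published_trials()$trial`.
#' @return A [trial_summary()].
#' @export
build_trial_fixture <- function(trial, traj = generate_fixture_trajectory()) {
  pub <- published_trials()
  row <- pub[pub$trial == trial, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown trial `", trial, "`; see published_trials()."))
  }
  schedule <- .fixture_visit_schedules()[[trial]]
  s <- row$delay_at_final_weeks / row$duration_weeks
  simulate_trial(
    traj,
    anchor_time = anchor_baseline(traj, row$baseline_mean_cdr_sb),
    visit_weeks = schedule,
    s = s,
    trial_name = row$trial,
    treatment = row$treatment
  )
}

#' Materialize all synthetic fixtures
#'
#' Writes the calibrated synthetic trajectory, the three trial fixtures and
#' a subject-level cohort CSV into `dir`. Idempotent for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the subject-level cohort.
#' @param n_subjects,visits_per_subject Cohort dimensions for the subject
#'   CSV.
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixtures <- function(dir, seed = 1, n_subjects = 100, visits_per_subject = 4) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- generate_fixture_trajectory()
  paths <- character(0)

  p <- file.path(dir, "natural_history_synthetic.json")
  write_trajectory(traj, p)
  paths <- c(paths, p)

  for (trial in published_trials()$trial) {
    ts <- build_trial_fixture(trial, traj)
    slug <- tolower(gsub("[^A-Za-z0-9]+", "_", trial))
    p <- file.path(dir, paste0("trial_", slug, "_synthetic.json"))
    write_trial_summary(ts, p)
    paths <- c(paths, p)
  }

  subjects <- simulate_subjects(
    traj, n_subjects = n_subjects, visits_per_subject = visits_per_subject,
    seed = seed
  )
  p <- file.path(dir, "subjects_synthetic.csv")
  readr::write_csv(
    dplyr::rename(subjects, disease_time_years = "disease_time"), p
  )
  paths <- c(paths, p)

  invisible(paths)
}

#' Path to a packaged synthetic fixture
#'
#' @param file Fixture file name, e.g. `"natural_history_synthetic.json"` or
#'   `"trial_clarity_ad_synthetic.json"`; `NULL` lists the available files.
#' @return A file path (or a vector of available file names).
#' @export
fixture_path <- function(file = NULL) {
  dir <- system.file("extdata", package = "adtimesave")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) abort(paste0("No packaged fixture named `", file, "`."))
  path
}
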