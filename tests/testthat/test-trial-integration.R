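toy_linear_trial <- function(slope = 0.04, weeks = seq(0, 80, by = 10),
                             active_final_offset = -0.6, baseline = 3) {
  placebo <- slope * weeks
  active <- slope * weeks
  active[length(active)] <- placebo[length(placebo)] + active_final_offset
  trial_summary(
    data.frame(
      arm = rep(c("placebo", "active"), each = length(weeks)),
      week = rep(weeks, 2),
      mean_change = c(placebo, active)
    ),
    trial_name = "toy", baseline_mean_cdr_sb = baseline
  )
}

test_that("packaged trial fixtures read back with their published baseline and duration", {
  clarity <- read_trial_summary(fixture_path("trial_clarity_ad_synthetic.json"))
  expect_equal(clarity$duration_weeks, 79)
  expect_equal(clarity$baseline_mean_cdr_sb, 3.22)
  expect_identical(clarity$treatment, "Lecanemab")
  expect_setequal(unique(clarity$arms$arm), c("placebo", "active"))

  # round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_trial_summary(clarity, p)
  back <- read_trial_summary(p)
  expect_equal(back$arms, clarity$arms)
  expect_equal(back$baseline_mean_cdr_sb, clarity$baseline_mean_cdr_sb)

  # invariant violations are parse errors
  bad <- data.frame(
    arm = rep(c("placebo", "active"), each = 3),
    week = c(0, 20, 10, 0, 10, 20),
    mean_change = c(0, 0.5, 0.3, 0, 0.2, 0.4)
  )
  expect_error(trial_summary(bad, "bad", 3), "strictly increasing")
  bad0 <- data.frame(
    arm = rep(c("placebo", "active"), each = 2),
    week = c(5, 20, 5, 20), mean_change = c(0, 1, 0, 1)
  )
  expect_error(trial_summary(bad0, "bad", 3), "week 0")
})

test_that("the final-visit delay has a closed form on a linear placebo decline", {
  trial <- toy_linear_trial()
  eff <- estimate_final_visit_delay(trial)
  expect_equal(eff$delay_at_final_weeks, 0.6 / 0.04, tolerance = 1e-6)
  expect_equal(eff$time_saving_fraction, 15 / 80, tolerance = 1e-6)
  expect_false(eff$active_worse)

  # identical arms: zero delay
  same <- toy_linear_trial(active_final_offset = 0)
  eff0 <- estimate_final_visit_delay(same)
  expect_equal(eff0$delay_at_final_weeks, 0, tolerance = 1e-8)
  expect_equal(eff0$time_saving_fraction, 0, tolerance = 1e-8)

  # active worse: negative delay with a warning
  worse <- toy_linear_trial(active_final_offset = 0.4)
  expect_warning(effw <- estimate_final_visit_delay(worse), "negative delay")
  expect_equal(effw$delay_at_final_weeks, -0.4 / 0.04, tolerance = 1e-6)
  expect_true(effw$active_worse)
})

test_that("a horizontally shifted active series is recovered exactly on a linear segment", {
  weeks <- seq(0, 80, by = 10)
  slope <- 0.05
  shift <- 12
  placebo <- slope * weeks
  active <- slope * pmax(0, weeks - shift)
  trial <- trial_summary(
    data.frame(
      arm = rep(c("placebo", "active"), each = length(weeks)),
      week = rep(weeks, 2), mean_change = c(placebo, active)
    ),
    trial_name = "shifted", baseline_mean_cdr_sb = 3
  )
  eff <- estimate_final_visit_delay(trial)
  expect_equal(eff$delay_at_final_weeks, shift, tolerance = 1e-6)
})

test_that("time saving is the unit-free delay/duration ratio", {
  expect_equal(round(100 * time_saving(33, 76)), 43)
  expect_equal(round(100 * time_saving(5.3, 18)), 29)
  expect_equal(round(100 * time_saving(24.3, 79)), 31)
  expect_equal(time_saving(0, 76), 0)
  # invariant to units
  expect_equal(time_saving(33, 76), time_saving(weeks_to_years(33), weeks_to_years(76)))
  expect_equal(time_saving(6, 18), time_saving(months_to_years(6), months_to_years(18)))
  expect_error(time_saving(5, 0), "positive")
})

test_that("the delay estimator recovers the true time saving on noiseless simulated trials", {
  traj <- fixture_traj()
  anchor <- anchor_baseline(traj, 3.22)
  for (s_true in c(0.1, 0.2, 0.3, 0.4)) {
    trial <- simulate_trial(traj, anchor, visit_weeks = seq(0, 78, by = 13), s = s_true)
    eff <- estimate_final_visit_delay(trial)
    expect_equal(eff$time_saving_fraction, s_true, tolerance = 0.02)
  }
})

test_that("fixtures calibrated through the published delays reproduce them", {
  traj <- fixture_traj()
  tb <- read_trial_summary(fixture_path("trial_trailblazer_alz_2_synthetic.json"))
  eff <- estimate_final_visit_delay(tb)
  expect_equal(eff$delay_at_final_weeks, 30.1, tolerance = 1.5)
  expect_equal(round(100 * eff$time_saving_fraction), 40)
})

test_that("trial baselines anchor at the published disease times", {
  traj <- fixture_traj()
  expect_equal(anchor_baseline(traj, 3.22), 10.7, tolerance = 1e-6)
  expect_equal(anchor_baseline(traj, 2.49), 10.0, tolerance = 1e-6)
  expect_equal(anchor_baseline(traj, nh_evaluate(traj, 0)), 0, tolerance = 1e-6)
  expect_error(anchor_baseline(traj, 19), "achievable")
})

test_that("placebo extrapolation shifts the trajectory to match the final visit", {
  traj <- fixture_traj()
  # fixture placebo follows the trajectory: shift should be ~0
  clarity <- read_trial_summary(fixture_path("trial_clarity_ad_synthetic.json"))
  shifted <- extrapolate_placebo(traj, clarity)
  expect_equal(attr(shifted, "shift"), 0, tolerance = 1e-6)

  # local linear oracle: placebo 0.2 points below the trajectory at the
  # final visit on a segment of slope 0.1/year -> 2-year shift to later times
  lin <- nh_trajectory(data.frame(time_years = c(0, 50, 100), cdr_sb = c(0, 5, 10)))
  weeks <- seq(0, 104, by = 26)
  yrs <- weeks_to_years(weeks)
  anchor <- 30
  base <- nh_evaluate(lin, anchor)
  placebo <- nh_evaluate(lin, anchor + yrs) - base
  placebo[length(placebo)] <- placebo[length(placebo)] - 0.2
  active <- placebo
  trial <- trial_summary(
    data.frame(
      arm = rep(c("placebo", "active"), each = length(weeks)),
      week = rep(weeks, 2), mean_change = c(placebo, active)
    ),
    trial_name = "lin", baseline_mean_cdr_sb = base
  )
  shifted2 <- extrapolate_placebo(lin, trial, anchor_time = anchor)
  expect_equal(attr(shifted2, "shift"), 0.2 / 0.1, tolerance = 1e-6)
  expect_equal(
    nh_evaluate(shifted2, anchor + weeks_to_years(104)),
    base + placebo[length(placebo)],
    tolerance = 1e-8
  )

  # placebo years to severe dementia on the packaged fixtures match the
  # published projections to the fixture-construction tolerance
  emerge <- read_trial_summary(fixture_path("trial_emerge_synthetic.json"))
  sh <- extrapolate_placebo(traj, emerge)
  expect_equal(nh_invert(sh, 16) - attr(sh, "anchor_time"), 7.6, tolerance = 0.2)
})
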