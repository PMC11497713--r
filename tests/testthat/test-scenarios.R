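# Worked-example configuration: 6-month delay at the end of an 18-month
# trial (s = 1/3), anchored at an early-symptomatic baseline.
worked_example <- function(kind, ...) {
  traj <- fixture_traj()
  spec <- scenario_spec(
    kind, time_saving_fraction = 6 / 18, trial_end_years = months_to_years(18), ...
  )
  scenario_trajectory(traj, spec, anchor_time = anchor_baseline(traj, 3.22))
}

test_that("continued slowing delays progression by 12 months at 36 months (s = 1/3)", {
  st <- worked_example("continued_slowing")
  expect_equal(years_to_months(cumulative_delay(st, months_to_years(36))), 12,
               tolerance = 1e-9)
  # the identity delay(t) = s * t holds exactly
  tt <- c(0.2, 1.5, 3, 7, 11)
  expect_equal(cumulative_delay(st, tt), (1 / 3) * tt, tolerance = 1e-12)
})

test_that("fading slowing reproduces the 11/14/15-month worked example and its analytic integral", {
  st <- worked_example("fading_slowing", fade_horizon_years = months_to_years(72))
  got <- years_to_months(cumulative_delay(st, months_to_years(c(36, 54, 72))))
  expect_equal(got, c(11, 14, 15), tolerance = 1e-9)
  # no further accrual after the fade horizon
  expect_equal(years_to_months(cumulative_delay(st, months_to_years(90))), 15,
               tolerance = 1e-9)

  # analytic-integral oracle agreement over random configurations
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- runif(1, 0.05, 0.6)
      T_end <- runif(1, 0.5, 2)
      T16 <- T_end + runif(1, 2, 8)
      traj <- fixture_traj()
      spec <- scenario_spec("fading_slowing", time_saving_fraction = s,
                            trial_end_years = T_end, fade_horizon_years = T16)
      st_i <- scenario_trajectory(traj, spec, anchor_time = 10)
      tt <- seq(T_end, T16 + 1, length.out = 13)
      expect_equal(cumulative_delay(st_i, tt),
                   fading_delay_oracle(tt, s, T_end, T16),
                   tolerance = 1e-9)
    }
  })
})

test_that("zero effect collapses every scenario onto placebo", {
  traj <- fixture_traj()
  for (kind in c("enduring_delay", "fading_slowing", "continued_slowing")) {
    spec <- scenario_spec(kind, time_saving_fraction = 0, trial_end_years = 1.5)
    st <- scenario_trajectory(traj, spec, anchor_time = 10)
    tt <- c(0, 1.5, 3, 6)
    expect_equal(cumulative_delay(st, tt), rep(0, 4), tolerance = 1e-9)
    expect_equal(scenario_score(st, tt), nh_evaluate(traj, 10 + tt), tolerance = 1e-9)
    expect_equal(st$T_active, st$T_p, tolerance = 1e-6)
  }
})

test_that("an enduring delay is constant after the trial and shifts milestones by d_end", {
  st <- worked_example("enduring_delay")
  tt <- seq(1.5, 8, by = 0.5)
  expect_equal(cumulative_delay(st, tt), rep(0.5, length(tt)))
  expect_equal(st$T_active - st$T_p, 0.5, tolerance = 1e-9)
})

test_that("all scenarios agree at the end of the trial and order conservatively thereafter", {
  kinds <- c("enduring_delay", "fading_slowing", "continued_slowing")
  sts <- lapply(kinds, worked_example)
  names(sts) <- kinds
  T_end <- months_to_years(18)
  d_at_end <- vapply(sts, cumulative_delay, numeric(1), t = T_end)
  expect_equal(unname(d_at_end), rep(0.5, 3), tolerance = 1e-9)

  tt <- seq(T_end, 10, length.out = 40)
  de <- cumulative_delay(sts$enduring_delay, tt)
  df <- cumulative_delay(sts$fading_slowing, tt)
  dc <- cumulative_delay(sts$continued_slowing, tt)
  expect_true(all(de <= df + 1e-9))
  expect_true(all(df <= dc + 1e-9))
  # same ordering for milestone delays
  delays <- vapply(sts, function(s) s$T_active - s$T_p, numeric(1))
  expect_true(delays[1] <= delays[2] && delays[2] <= delays[3])
  # cumulative delay non-decreasing for s >= 0
  expect_true(all(diff(df) >= -1e-9))
})

test_that("the fading fixed point matches the closed-form self-consistent horizon", {
  st <- worked_example("fading_slowing")
  T16_expected <- fading_milestone_oracle(st$T_p, 1 / 3, months_to_years(18))
  expect_equal(st$fade_T16, T16_expected, tolerance = 1e-5)
  expect_equal(st$T_active, T16_expected, tolerance = 1e-5)
  # delay accrual is capped once the treated arm reaches the milestone
  expect_equal(
    cumulative_delay(st, st$T_active + 2),
    cumulative_delay(st, st$T_active),
    tolerance = 1e-9
  )
})

test_that("hypothetical continued slowing reproduces the published intervention delays", {
  traj <- fixture_traj()
  res <- hypothetical_intervention(traj, c(0, 5, 10, 15), s = 0.30,
                                   kind = "continued_slowing")
  expect_equal(round(res$delay_years, 1), c(7.6, 5.4, 3.3, 1.2))
  # closed form (T16 - start) * s / (1 - s), via the trajectory
  Tp <- 17.7 - c(0, 5, 10, 15)
  expect_equal(res$delay_years, Tp * 0.3 / 0.7, tolerance = 1e-5)

  none <- hypothetical_intervention(traj, c(0, 10), s = 0, kind = "continued_slowing")
  expect_equal(none$delay_years, c(0, 0), tolerance = 1e-9)
  expect_error(
    hypothetical_intervention(traj, 20, s = 0.3, kind = "continued_slowing"),
    "past the milestone"
  )
})

test_that("earlier intervention yields at least as much milestone delay", {
  traj <- fixture_traj()
  starts <- c(0, 4, 8, 12, 16)
  for (kind in c("continued_slowing", "fading_slowing")) {
    res <- hypothetical_intervention(traj, starts, s = 0.30, kind = kind)
    expect_true(all(diff(res$delay_years) <= 1e-9), info = kind)
  }
})

test_that("milestone delays and brackets reproduce the published enduring-delay column", {
  traj <- fixture_traj()
  pub <- published_trials()
  expected_delay <- c(0.3, 0.5, 0.6)
  expected_lower <- c(0.2, 0.3, 0.4)
  expected_upper <- c(0.5, 0.6, 0.7)
  for (i in seq_len(nrow(pub))) {
    trial <- build_trial_fixture(pub$trial[i], traj)
    anchor <- anchor_baseline(traj, pub$baseline_mean_cdr_sb[i])
    placebo <- extrapolate_placebo(traj, trial, anchor)
    spec <- scenario_spec(
      "enduring_delay",
      time_saving_fraction = pub$delay_at_final_weeks[i] / pub$duration_weeks[i],
      trial_end_years = weeks_to_years(pub$duration_weeks[i])
    )
    st <- scenario_trajectory(placebo, spec, anchor, trial)
    res <- delay_to_severe_dementia(placebo, st)
    expect_equal(round(res$delay_years, 1), expected_delay[i])
    expect_equal(round(res$delay_lower, 1), expected_lower[i])
    expect_equal(round(res$delay_upper, 1), expected_upper[i])
  }
})

test_that("uncertainty bands collapse at delta 0 and widen monotonically", {
  traj <- fixture_traj()
  f <- function(s) {
    spec <- scenario_spec("continued_slowing", time_saving_fraction = s,
                          trial_end_years = 1.5)
    st <- scenario_trajectory(traj, spec, anchor_time = 10)
    st$T_active - st$T_p
  }
  b0 <- uncertainty_band(f, s = 0.3, delta = 1e-12)
  expect_equal(b0$lower, b0$upper, tolerance = 1e-6)
  widths <- vapply(c(0.05, 0.1, 0.2), function(d) {
    b <- uncertainty_band(f, 0.3, d)
    b$upper - b$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(uncertainty_band(f, 0.95, 0.1), "inside")
})

test_that("projected differences splice continuously at the trial end and fade at the ceiling", {
  traj <- fixture_traj()
  clarity <- read_trial_summary(fixture_path("trial_clarity_ad_synthetic.json"))
  anchor <- anchor_baseline(traj, clarity$baseline_mean_cdr_sb)
  placebo <- extrapolate_placebo(traj, clarity, anchor)
  eff <- estimate_final_visit_delay(clarity)
  T_end <- weeks_to_years(clarity$duration_weeks)
  for (kind in c("enduring_delay", "fading_slowing", "continued_slowing")) {
    spec <- scenario_spec(kind, time_saving_fraction = eff$time_saving_fraction,
                          trial_end_years = T_end)
    st <- scenario_trajectory(placebo, spec, anchor, clarity)
    at_end <- projected_difference_at(placebo, st, horizons = T_end)
    expect_equal(at_end$cdr_sb_difference, eff$cdr_sb_difference_at_final,
                 tolerance = 1e-6, info = kind)
    expect_equal(at_end$delay_years, weeks_to_years(eff$delay_at_final_weeks),
                 tolerance = 1e-6, info = kind)
  }

  # continued slowing, s = 1/3: 12-month delay at the 36-month horizon
  st_c <- worked_example("continued_slowing")
  pd <- projected_difference_at(st_c$placebo_traj, st_c, horizons = 3)
  expect_equal(years_to_months(pd$delay_years), 12, tolerance = 1e-9)

  # enduring difference shrinks toward 0 as both arms reach the ceiling
  spec_e <- scenario_spec("enduring_delay",
                          time_saving_fraction = eff$time_saving_fraction,
                          trial_end_years = T_end)
  st_e <- scenario_trajectory(placebo, spec_e, anchor, clarity)
  pd_e <- projected_difference_at(placebo, st_e, horizons = c(4, 8, 11))
  expect_true(all(diff(abs(pd_e$cdr_sb_difference)) < 0))
  expect_lt(abs(pd_e$cdr_sb_difference[3]), 0.05)
  expect_error(projected_difference_at(placebo, st_e, horizons = -1), "baseline")
})

test_that("the stage-dependent fade mode behaves like a fade", {
  traj <- fixture_traj()
  spec <- scenario_spec("fading_slowing", time_saving_fraction = 0.3,
                        trial_end_years = 0, fade_mode = "cdr_stage")
  st <- scenario_trajectory(traj, spec, anchor_time = 5)
  spec_c <- scenario_spec("continued_slowing", time_saving_fraction = 0.3,
                          trial_end_years = 0)
  st_c <- scenario_trajectory(traj, spec_c, anchor_time = 5)
  tt <- seq(0.5, 10, by = 0.5)
  d_fade <- cumulative_delay(st, tt)
  # a fade accrues less than continued slowing, never decreases
  expect_true(all(d_fade <= cumulative_delay(st_c, tt) + 1e-9))
  expect_true(all(diff(d_fade) >= -1e-9))
  expect_gt(st$T_active - st$T_p, 0)
  expect_lt(st$T_active, st_c$T_active)

  # zero effect: no delay
  spec0 <- scenario_spec("fading_slowing", time_saving_fraction = 0,
                         trial_end_years = 0, fade_mode = "cdr_stage")
  st0 <- scenario_trajectory(traj, spec0, anchor_time = 5)
  expect_equal(cumulative_delay(st0, c(1, 5)), c(0, 0), tolerance = 1e-9)
})

test_that("scenario specs validate their invariants", {
  expect_error(scenario_spec("continued_slowing", time_saving_fraction = 1,
                             trial_end_years = 1.5), "never progresses")
  expect_error(scenario_spec("enduring_delay", time_saving_fraction = 0.3,
                             delay_at_final_years = 0.2, trial_end_years = 1.5),
               "disagree")
  sp <- scenario_spec("enduring_delay", delay_at_final_years = 0.45,
                      trial_end_years = 1.5)
  expect_equal(sp$s, 0.3)
  expect_error(scenario_spec("fading_slowing", time_saving_fraction = 0.3,
                             trial_end_years = 2, fade_horizon_years = 1),
               "after the end")
})
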