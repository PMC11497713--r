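# adtimesave

Projecting the long-term efficacy of amyloid-targeting therapies in
Alzheimer's disease on the natural-history timeline of the CDR-SB score.

Recent phase 3 trials of high-clearance amyloid-beta antibodies (aducanumab,
lecanemab, donanemab) slowed decline on the Clinical Dementia Rating–Sum of
Boxes (CDR-SB, 0–18) over roughly 18 months, but their impact beyond the
trial window is unobserved. `adtimesave` implements a framework that makes
the long-term question explicit: trial results are expressed as *time saved*
relative to the natural course of the disease, and long-term benefit is
projected under clearly stated scenarios spanning conservative to
optimistic.

The framework, for a trial of duration \(T\):

1. **Natural-history trajectory.** A monotone curve \(F(t)\) maps disease
   time \(t\) (years since crossing the amyloid-PET positivity threshold,
   24.1 Centiloids) to mean CDR-SB. It can be fit from staged longitudinal
   data with a mixed-effects model — mean curve a natural cubic spline with
   5 degrees of freedom plus a patient-level random intercept
   (`fit_mean_trajectory()`) — or supplied as knot points.
2. **Time delay at the final visit.** From the published per-visit adjusted
   mean changes, the placebo series is interpolated with a natural cubic
   spline and the delay is \(d = T - t^\*\), where \(t^\*\) is the earliest
   time the placebo curve reaches the active arm's final mean change
   (`estimate_final_visit_delay()`). The **time saving** is \(s = d / T\).
3. **Anchoring and placebo extrapolation.** The trial baseline mean locates
   the population on the disease timeline via \(F^{-1}\)
   (`anchor_baseline()`); after the final visit the placebo arm follows a
   horizontally shifted copy of \(F\) matched at the final visit
   (`extrapolate_placebo()`).
4. **Scenarios.** Past the trial end the active arm accrues delay
   \(D(t)\) under one of three rules (`scenario_trajectory()`):
   - *enduring delay* (conservative): \(D(t) = d\);
   - *fading slowing* (intermediate): the instantaneous saving rate falls
     linearly from \(s\) at the trial end to 0 when the treated arm reaches
     CDR-SB 16, so
     \(D(t) = d + s\,(t - T)\,\bigl(T_{16} - \tfrac{t + T}{2}\bigr)/(T_{16} - T)\)
     up to the (self-consistently solved) milestone time \(T_{16}\);
   - *continued slowing* (optimistic): \(D(t) = s\,t\).
5. **Milestones.** Per-arm times to severe dementia (CDR-SB ≥ 16) and the
   treatment-associated delay, with an uncertainty bracket from re-running
   the scenario at \(s \mp 10\) percentage points
   (`delay_to_severe_dementia()`, `milestone_table()`).

The package ships calibrated *synthetic* stand-ins for inputs that are not
published at full precision (see `generate_fixture_trajectory()`,
`build_trial_fixture()`); everything needed runs offline.

## Worked example

```r
library(adtimesave)

traj <- generate_fixture_trajectory()       # synthetic CDR-SB natural history
clarity <- read_trial_summary(fixture_path("trial_clarity_ad_synthetic.json"))

estimate_final_visit_delay(clarity)
#> <treatment_effect> CLARITY AD: delay 24.3 weeks over 79 weeks (time saving 31%)
```

A 24.3-week delay over a 79-week trial is a 31% time saving: the active arm
reached the placebo arm's disease state about 5.6 months later. Projecting
all three packaged trials to the severe-dementia milestone:

```r
trials <- lapply(
  c("trial_emerge_synthetic.json", "trial_clarity_ad_synthetic.json",
    "trial_trailblazer_alz_2_synthetic.json"),
  function(f) read_trial_summary(fixture_path(f))
)
round_report(milestone_table(trials, traj))
#>   trial             treatment  time_saving_fraction placebo_years enduring ...
#> 1 EMERGE            Aducanumab                0.201           7.7      0.3
#> 2 CLARITY AD        Lecanemab                 0.308           7.0      0.5
#> 3 TRAILBLAZER-ALZ 2 Donanemab                 0.396           6.6      0.6
```

`placebo_years` is the projected time from the trial baseline until the
untreated arm reaches CDR-SB 16; the `enduring`, `fading` and `continued`
columns are the projected treatment-associated delays in years under each
scenario (with `_lower`/`_upper` bracket columns at ±10 points of time
saving). Hypothetical earlier intervention shows why treating sooner matters
when benefits accumulate:

```r
hypothetical_intervention(traj, c(0, 5, 10, 15), s = 0.30,
                          kind = "continued_slowing")
#> delay_years: 7.6, 5.4, 3.3, 1.2   (intervening 0/5/10/15 y after positivity)
```

`autoplot()` methods are available for trajectories, trial summaries and
scenario extrapolations; `tidy()`/`glance()` give tabular access to fitted
objects.

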