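---
title: "Projecting long-term treatment effects on the CDR-SB natural-history timeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting long-term treatment effects on the CDR-SB natural-history timeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtimesave)
```

## The modelling problem

Phase 3 trials of amyloid-targeting antibodies report adjusted mean CDR-SB
trajectories over roughly 18 months. Two features make their long-term
interpretation hard: the CDR-SB natural history is strongly non-linear over
the ~20-year disease course, so a fixed score difference means different
things at different stages; and nothing beyond the trial window is
observed. `adtimesave` addresses both by re-expressing the trial effect as
*time*: how far behind the placebo arm's disease state the treated arm sits
at the final visit, and what that delay becomes under explicit
extrapolation rules.

All internal computation is in years (1 year = 52.1786 weeks = 12 months);
conversions happen only at I/O boundaries, and published-table rounding
(years to 1 decimal, percent to integers) is applied only by
`round_report()` at render time.

## The natural-history trajectory

A trajectory is a monotone map from disease time — years since the mean
amyloid-PET curve crosses the 24.1-Centiloid positivity threshold — to mean
CDR-SB. It is stored as knot points at ≤ 0.5-year spacing and interpolated
with a natural cubic spline. Storage as dense `(time, score)` pairs rather
than basis coefficients makes the on-disk format independent of how a curve
was originally estimated, with negligible interpolation error at that
spacing.

Numerical choices:

* **Monotonicity.** Inversion (anchoring, milestone times) requires a
  monotone curve. If the natural spline through user-supplied knots has a
  decreasing segment (checked on a fine derivative grid), the constructor
  warns and falls back to Fritsch–Carlson monotone cubic interpolation.
* **Extrapolation.** Before the first knot the curve is held at the first
  knot score (the CDR-SB floor of the represented disease stage); past the
  last knot it continues linearly with the end slope, clipped at the scale
  maximum 18. Evaluation is limited to a window from 2 years before the
  first knot to 5 years after the last, which covers every projection the
  package produces while refusing far-field extrapolations that the data
  cannot support.
* **Inversion.** Bisection to 1e-8 years; flat segments resolve to their
  earliest time. Tests verify the round trip `invert(evaluate(t)) = t` to
  1e-6 years and agreement of the spline evaluation with an independent
  tridiagonal-solver oracle to 1e-9.

### Fitting from subject-level data

`fit_mean_trajectory()` estimates the mean curve from staged longitudinal
records with a Gaussian random-intercept model: a natural cubic spline mean
with 5 degrees of freedom (intercept included) and a patient-level random
intercept, fit by REML with `lme4`. Knot placement is not dictated by the
model class; we use the conventional quantile rule (boundary knots at the 0
and 1 quantiles of observed times, internal knots at 0.25/0.5/0.75). The
fitted mean is tabulated on a 0.5-year grid, monotonized with a running
maximum (basis wiggles in sparsely observed tails are not interpretable as
disease progression) and clipped to [0, 18]. `prediction_interval()`
combines intercept and residual variances into the patient-level band shown
around such curves.

## Trial integration

`estimate_final_visit_delay()` interpolates the placebo mean-change series
with a natural cubic spline and locates, by bisection, the earliest study
time at which the placebo curve equals the active arm's final-visit mean
change; the delay is the trial duration minus that time, and the time
saving is delay over duration. Choices worth stating:

* If the placebo spline is non-monotone the crossing may be ambiguous; the
  interpolant falls back to monotone cubic, and where multiple crossings
  would still exist the earliest is reported.
* An active arm that progressed *more* than placebo yields a negative delay
  (via linear continuation of the placebo end slope) with a warning, so
  unfavourable trials flow through the same pipeline.
* Anchoring uses the trial's mean baseline CDR-SB and the trajectory
  inverse; placebo extrapolation shifts the trajectory horizontally to pass
  through the placebo arm's absolute score at the final visit. Within the
  trial window observed series take precedence over the shifted curve.

## The three scenarios

With trial-end time $T$, final-visit delay $d = sT$ and time saving $s$,
the cumulative delay $D(t)$ of the treated arm after the trial is:

| Scenario | Rule | Reading |
|---|---|---|
| enduring delay | $D(t) = d$ | benefit stops accruing (conservative) |
| fading slowing | rate falls linearly from $s$ to 0 at the treated milestone time | benefit fades with stage (intermediate) |
| continued slowing | $D(t) = s\,t$ | proportional slowing persists (optimistic) |

All three agree with the observed delay at $t = T$, and for $s \ge 0$ are
ordered enduring ≤ fading ≤ continued at every later time — properties the
test suite asserts directly.

The fading rule integrates to
$D(t) = d + s\,(t-T)\,\bigl(T_{16} - \tfrac{t+T}{2}\bigr)/(T_{16}-T)$ for
$T \le t \le T_{16}$, constant thereafter. The fade horizon $T_{16}$ — the
time the *treated* arm reaches CDR-SB 16 — itself depends on the fade, so
it is solved by damped fixed-point iteration (seeded with the
continued-slowing milestone time, tolerance 1e-6 years, at most 200
iterations); a closed form exists for the linear-in-time rule and serves as
a test oracle. Delay accrual is capped at the milestone score 16 even
though the trajectory itself continues to the scale maximum 18: the fade is
defined relative to the severe-dementia milestone, and letting delays keep
accruing between 16 and 18 would contradict the 0%-saving endpoint of the
rule.

Two fade variables are conceivable and the package provides both
(`fade_mode`): the default fades linearly in treated (calendar) time, which
exactly reproduces the canonical 11/14/15-month worked example; the
alternative `cdr_stage` mode makes the instantaneous rate proportional to
the remaining CDR-SB distance to the milestone, coupling rate and stage
through an ODE that is integrated with fixed-step RK4 (step 0.005 years).
Stage-dependent published figures are not exactly reproducible from either
rule, so neither is used for calibration; the default is the rule with the
exact worked example.

`hypothetical_intervention()` applies the continued or fading rule from an
arbitrary disease stage with no trial window ($T = 0$, $d = 0$), which is
how stage-dependence of the long-term benefit is explored: under continued
slowing the milestone delay is $(T_{16}-t_0)\,s/(1-s)$, largest for the
earliest intervention.

Uncertainty in the extracted time saving is propagated by re-running every
scenario at $s \mp 0.10$ (`uncertainty_band()`); for the enduring scenario
the final-visit delay is rescaled to $(s \mp 0.10)\,T$. Ten percentage
points approximates the reported 95% confidence half-width of patient-level
time-saving estimates in comparable trials.

## Synthetic calibration data

Two inputs behind the published projections are not available at full
precision: the estimated natural-history trajectory (published only as
anchor values) and the intermediate trial visit means (published as
graphs). The package therefore generates calibrated synthetic stand-ins:

* `generate_fixture_trajectory()` interpolates the published anchor points
  — (0 y, 0), (10.0, 2.49), (10.7, 3.22), (11.1, 3.68), (17.7, 16.0),
  (21.0, 18.0) — with a monotone cubic spline, tabulated at 0.25-year
  spacing. Monotone interpolation (rather than a parametric sigmoid) passes
  the anchors exactly; the local shape between anchors is not identified by
  the published values and should not be over-interpreted.
* `build_trial_fixture()` generates both arms of each packaged trial from
  that trajectory: placebo follows the trajectory from the anchored
  baseline, the active arm follows it at a slower pace calibrated so the
  final-visit delay equals the published estimate. The published baseline,
  duration and delay are thereby preserved; the final-visit score
  difference is approximate. Fixture filenames carry `_synthetic`.
* `simulate_subjects()` emulates a staged longitudinal cohort: trajectory
  mean plus subject intercept (SD 1.0) plus residual (SD 0.5), rounded to
  the half-point CDR-SB grid and clipped to [0, 18]. The default
  observation window of 6–18 years since positivity spans late-preclinical
  to severe dementia; below ~6 years the mean trajectory sits within one
  rounding increment of the floor, where clipping would bias a Gaussian
  fit and the score carries little information.

What passing tests on these data do and do not show: parameter-recovery
tests (time-saving recovery to ±0.02 on noiseless means; mean-curve
recovery within 0.15 CDR-SB at interior knots and intercept SD within 20%
at 500 subjects) validate the estimation machinery, not the biology. The
generators do not emulate informative dropout, cohort selection effects,
practice effects, or within-subject slope heterogeneity, and the synthetic
trajectory's shape between anchors is a modelling convention. Published
projections that depend on the unavailable exact trajectory (the fading and
continued milestone columns, full-precision final-visit delays) are
reproduced only to approximate tolerances (±0.2 y placebo milestone times,
±0.3–0.4 y scenario delays, ±1.5 weeks delays), and the tests assert
exactly that.

## Problem sizes

The simulation studies in the test suite use 500 subjects × 4 visits for
trajectory-fit recovery and 7–20-visit summary series for estimator
recovery; these sizes give Monte-Carlo error comfortably below the asserted
tolerances while keeping the whole suite fast.

## Known limitations

* Mean-trajectory reasoning throughout: results describe an average
  patient, not individual-level heterogeneity in progression or response.
* No mortality or dropout adjustment; projected milestone times condition
  on survival to the milestone.
* Trial inputs are summary-level marginal means; standard errors of the
  extracted time savings are not available, which is why uncertainty is
  handled by the ±10-point bracket rather than sampling-based intervals.
* The trajectory inverse is only defined over the achieved score range;
  trials in populations outside the represented disease window cannot be
  anchored.
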