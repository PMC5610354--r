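---
title: "Methods: BACI evaluation of at-home telemonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BACI evaluation of at-home telemonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telebaci)
```

## The design and its assumptions

A before-and-after control-intervention (BACI) design observes each subject
for a long pre-period and a post-period, with matched controls observed over
the same clock. It suits heterogeneous chronically ill populations where
randomisation is infeasible: the contrast of interest is a change in each
arm's *trajectory* at the intervention, and the control arm plus the per-bin
control−test difference series guard against secular and seasonal trends.

The analysis assumes:

* outcomes drift roughly linearly on a variance-stabilised scale over the
  3-year pre-period (chronically ill patients age and spend more);
* events synchronised to each patient's own start date average out seasonal
  effects across patients;
* cross-patient bin means, after transformation, have approximately normal,
  homoscedastic, independent residuals around the segmented trend. Plain OLS
  is used deliberately — no autocorrelation correction — because the fitted
  unit is the cross-patient average of many sparse, weakly dependent
  per-patient streams.

## Binning conventions

Day 0 is the first monitored day. Bin `b` of width `w` covers days
`[b*w, (b+1)*w)`, strictly half-open, so an event never lands in two bins and
day 0 opens the after-period. Costs use `w = 30` with 36 before and 12 after
bins (≈3 years / 1 year); hospital admissions and length of stay use
`w = 100`, which avoids mostly-zero bins, with 11 before and 4 after bins
(1100 d ≈ 3 y, 400 d ≈ 1 y — the width is conventional, the counts are this
package's choice to mirror the 30-day horizons).

A death truncates a patient's streams. Bins cut short by death are flagged
*unobserved* and excluded from the cross-patient mean rather than zero-filled:
zero-filling would fabricate an expenditure decline out of mortality. A bin
observed by nobody is absent, and fits simply skip it.

## Transform selection

The model's real assumption is residual normality, so `select_transform()`
applies Shapiro–Wilk to the residuals of the segmented fit under each
candidate transform (identity, sqrt, log; log is dropped when any bin value
is nonpositive, sqrt when any is negative) and keeps the first of
identity → sqrt → log with p ≥ .05, else the best of them. Two caveats are
worth stating plainly: the test has modest power at 48 bins, so a gently
curved series can retain the identity scale; and in the pipeline cost
outcomes are fitted on the sqrt scale regardless (with the normality report
attached), both because right-skewed claims data are the textbook case for
it and because the downstream savings machinery is built on the resulting
quadratic back-transform. Difference (control−test) series are analysed
untransformed. Transformation is applied to the cross-patient mean series,
not per patient, matching the convention that the averaged series is the
unit of analysis.

## Segmented regression and the slope ANCOVA

`compare_slopes()` fits `y = b0 + b1 t + b2 A + b3 tA` with `A = [t >= 0]`
and tests `b3` (two-tailed t). This single model is exactly equivalent to
fitting the two periods separately, so `interaction_estimate` equals
`slope_after − slope_before` identically, and the partial F test of the
segmented model against the common-slope model satisfies `F = t²`; both
p-values are reported and tested for agreement to 1e-10.

Outliers: the stated analysis excludes them without giving a rule, so the
rule here is explicit and conservative — iteratively remove the bin with the
largest externally studentized residual exceeding 3, at most 10% of bins,
never below 3 remaining points, all removals logged. Exclusion happens once,
on the segmented model, before all fits, keeping the reported segment fits
and the interaction mutually consistent.

The "combined line vs before-only" contrast (used to show a control arm had
no before/after change) has no standard estimator because the two fits share
data; it is implemented as an approximate t on the difference of the two
slope estimates with combined standard errors and conservative degrees of
freedom, and is labelled approximate wherever it appears.

Prediction intervals use the standard OLS new-observation formula; their
95% coverage is verified by simulation (10,000 fresh draws) in the test
suite.

## Annualised curves and savings

A sqrt-scale fit `a + bt` back-transforms to a per-bin cost `(a+bt)²`;
multiplying by `365/w` gives an annual rate, quadratic in time. The order of
operations matters and is a deliberate choice: squaring first keeps the
units coherent (AUD, days, admissions — the unit tag is carried through and
never mixed) and yields the quadratic annual-cost curves the design
describes. Identity-scale fits bypass the squaring and are clipped at zero.

Savings over the year after intervention are the closed-form integral of the
area between the projected before-curve and the after-curve
(`∫(a+bt)² dt`, verified against adaptive quadrature to 1e-8 relative).
Two refinements:

* the curves' intersection is solved on the transform scale, where both are
  lines (`t* = (a2−a1)/(b1−b2)`); when it falls within the year, savings
  accrue only from that day — an intervention needs time to act, and
  anchoring at day 0 overstates the saving. Both totals then cover the
  `[start, 365 d]` window, so `saving = projected − actual` holds by
  construction;
* extrapolating a sqrt-scale line past a sign change would make the squared
  curve bounce upward, which is meaningless for costs; integration refuses
  with an error instead.

Difference-series savings are computed on the linear (identity) scale, since
differences are analysed untransformed; squaring a difference of arms has no
cost interpretation. `roi()` is the plain ratio of annual saving to annual
service cost.

## Mortality standardisation and rounding

ASDRs are deaths/population per 10-year band from a master register;
expected cohort deaths are `n_band × ASDR_band` summed, and the reduction is
`(expected − observed)/expected`. All chained computation is full precision;
rounding (half away from zero) is presentation only.

One subtlety is made explicit because it changes printed cells: published
standardisation tables are typically typeset by rounding the ASDR row to two
decimals and then computing and rounding each expected-deaths cell from the
rounded rates. On the shipped worked example that chain gives an expected
total of 13.68 (band cells 3.87, 4.60, 1.91, 2.86, 0.44), while full
precision gives 13.6749 → 13.67 with the third band at 1.90. Both paths give
a 41.5% reduction at one decimal. `expected_deaths(as_printed = TRUE)`
reproduces the typeset chain cell by cell; the default is full precision.
Similarly `crude_reduction(as_printed = TRUE)` compares rates rounded to one
decimal (48.5% on the worked example) where full precision gives 48.7%; both
are reported, the rounded one flagged.

## Matching

Candidates must match the test patient exactly on gender and diagnosis group
(hard constraints); among those, distance is `|Δage|/10 + |Δseifa|` with
configurable weights — the matching variables are standard, the metric is
this package's choice since none is prescribed. Assignment is greedy without
replacement in ascending test-patient age order, ties broken by patient id,
which makes it deterministic and testable; optimal (Hungarian) matching is a
non-goal at trial scale. Continuous age is used rather than age bands. Tests
with no eligible candidate are reported, never silently dropped. Multiple
controls are collapsed to one effective partner by per-bin averaging, bins
unobserved for a control (post-death) falling back to the mean of the rest.

## The synthetic cohort: what it emulates, and not

The generator's defaults state the world once:

* sqrt(30-day cost) drifts linearly from `baseline_sqrt_cost = 9` sqrt(AUD)
  at 3 years pre-intervention with slope 0.13 per bin, calibrated so the
  projected pre-intervention trajectory reaches ≈$2800/yr one year after
  start — the scale of a chronically ill claims cohort; the test arm's slope
  halves at day 0 (`delta = −0.065`), the control arm's is unchanged;
* per-patient, per-bin noise of 1 sqrt(AUD); a bin's total is split into
  Poisson(3)-many gamma-share claim events dated uniformly within the bin,
  so claims are realistically sparse while bin means keep the exact
  quadratic structure;
* overnight admissions: negative-binomial counts (size 4) at 0.9 per 100
  days, halved post-intervention for the test arm; LOS ≈ 6 days per stay;
  10% of attendances are non-overnight emergency visits, which the analysis
  excludes by definition of an admission;
* death: constant within-band hazard matching the register's annual ASDRs
  (band defaults are the worked example's register rates), applied over the
  whole −1080..+360 window as a censoring process.

It does **not** emulate calendar seasonality, autocorrelated per-patient
cost dynamics, fee-schedule inflation, admission-cost linkage, or
heterogeneous monitoring durations. A green parameter-recovery test
therefore establishes that the pipeline recovers planted trajectory changes
from data satisfying its own assumptions — not that real claims data satisfy
them.

## Numerical and degenerate-input conventions

* Perfect (zero-residual) fits short-circuit the outlier rule and give
  zero-width prediction intervals; constant series fit slope 0 with R² = 0.
* Paired comparisons with constant differences return p = 1 (all zero) or
  p = 0 (exact shift) rather than erroring inside the t test.
* Fisher's exact test replaces chi-square whenever an expected cell is
  below 5; a contingency table with a zero margin is an error.
* Identical seeds give byte-identical cohorts and reports; every stochastic
  step in the pipeline is seeded from the single configured seed.

## Known limitations

* The effective-control averaging gives each pair equal weight regardless of
  its number of controls.
* The combined-vs-before slope p-value is approximate (see above).
* Savings extrapolation is limited to one year; trajectories likely plateau
  beyond that, and the quadratic projection would overstate growth.
* Monte-Carlo acceptance checks (type-I error, power, coverage, recovery)
  are run at fixed seeds and the stated replicate counts; they verify
  calibration under the generator's stated world only.
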