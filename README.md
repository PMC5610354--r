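# telebaci

Before-and-after control-intervention (BACI) analysis of at-home
telemonitoring for chronically ill patients, built around Australian
health-claims data (MBS medical and PBS pharmaceutical benefits, hospital
admissions and length of stay). The package is aimed at health-services
researchers who want to evaluate a home-monitoring intervention against
matched usual-care controls when a randomised design is not available:
patients are heterogeneous, costs drift upward with age and morbidity, and
the effect of interest is a *change in trajectory*, not a level difference.

Individual claims records of this kind are confidential, so the package
ships a synthetic cohort generator that reproduces the statistical structure
the analysis assumes, making every stage testable end to end.

## The model

Each patient's events are synchronised to day 0, the first monitored day.
Costs are totalled into 30-day bins (hospital outcomes into 100-day bins,
which avoids mostly-zero bins), averaged across patients within each bin,
and variance-stabilised — for cost data the square root, chosen by
Shapiro–Wilk tests on regression residuals. On the transform scale the
binned series is modelled as a segmented linear trend,

    y(t) = b0 + b1 t + b2 [t >= 0] + b3 t [t >= 0],

where `t` is the signed bin number. The intervention effect is the slope
change `b3`, tested with a two-tailed t test (ANCOVA of slopes; the
equivalent partial F test is reported alongside). The same machinery is
applied to the test arm, the control arm, and the per-bin control−test
difference series, which needs no transform.

Back-transforming a sqrt-scale fit gives a quadratic annual rate curve
`rate(t) = (365/w)(a + bt)^2`. Projecting the pre-intervention curve one
year past day 0 and integrating the area between it and the post-intervention
curve (from the day the two curves intersect, when they do) yields the
model-based annual saving, the percent rate reduction at one year, and a
return-on-investment ratio against the service cost.

Mortality is compared by indirect standardisation: age-specific death rates
(ASDR = deaths/population per 10-year band) from a master register give the
cohort's expected deaths; observed deaths against that expectation give the
mortality reduction, alongside crude per-arm death rates.

## Worked example

```r
library(telebaci)

coh <- generate_cohort(cohort_config(n_test = 50, seed = 2))
coh
#> <telebaci_cohort> 150 patients (50 test), 16930 claims, 1431 admissions, 63 deaths

tests  <- coh$patients[coh$patients$arm == "test", ]
binned <- bin_events(coh$claims[coh$claims$patient_id %in% tests$patient_id, ],
                     tests, width = 30, n_before = 36, n_after = 12)
series <- transform_series(average_patients(binned, 30), "sqrt")
cmp    <- compare_slopes(series)
cmp
#> <slope_comparison> cost (sqrt scale, 30-day bins)
#>   slope before 0.1291, after 0.0941; change -0.03497 (p = 0.0397)
#>   combined-vs-before slope p = 0.0891
```

The generator planted a pre-intervention drift of 0.13 sqrt(AUD) per bin and
halved it at day 0 for the test arm; the fitted slope change of −0.035
(p = .04 at this small n) recovers roughly half the planted −0.065, as
expected from a 50-patient average. Converting the two segments to annual
cost curves:

```r
sv <- estimate_savings(annualize(cmp$fit_before), annualize(cmp$fit_after))
sv
#> <savings_estimate> cost: projected 2561.3, actual 2467.9 AUD over days [0, 365]
#>   saving 93.4 AUD (3.6%); rate reduction at 1 y: 6.1%
```

i.e. without intervention this cohort was headed for about $2561 of claims
per patient over the year; the refitted post-intervention curve accrues
$2468, a 3.6% saving and a 6.1% lower spending *rate* at the one-year mark.

The mortality worked example reproduces a printed standardisation table
exactly from its integer register rows:

```r
asdr <- compute_asdr(example_register())
expected_deaths(asdr, example_test_cohort(), observed_deaths = 8,
                as_printed = TRUE)
#> <mortality_comparison> (as printed) expected deaths 13.68; observed 8; saved 5.68 (reduction 41.5%)
```

`run_pipeline(analysis_config(...))` chains all of the above (simulate or
load CSVs, match controls, bin, fit, estimate savings, baseline windows,
mortality) into a JSON-serialisable report; a thin command-line wrapper
lives at `inst/cli/telebaci.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package — simulating a 100-test-patient matched cohort, fitting
the segmented regressions, estimating savings, and recomputing the
register-based mortality standardisation — and writes a JSON results file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` argument drives every stochastic step, so a given seed always
reproduces the same report.
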