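Package: telebaci
Title: Before-and-After Control-Intervention Analysis of At-Home Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating at-home telemonitoring of chronically ill
    patients with a before-and-after control-intervention (BACI) design on
    health-claims data: matched-cohort construction, intervention-synchronised
    binning of expenditure, admission and length-of-stay series, square-root
    transform segmented regression with ANCOVA slope tests, model-based annual
    savings estimated from back-transformed quadratic cost curves, and
    mortality comparison via age-specific death rates. Includes a synthetic
    cohort generator emulating the statistical structure the analysis assumes,
    so the full pipeline is testable without confidential patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
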