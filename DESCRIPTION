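Package: slumr
Title: Linear and Non-Linear Mendelian Randomization for Sleep Duration
    and Hyperuricemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the causal dose-response relationship
    between habitual sleep duration and hyperuricemia with genetic
    instruments. Implements the full analysis flow of a sex-stratified
    linear and non-linear Mendelian randomization study: cross-sectional
    odds-ratio and restricted-cubic-spline modelling, genetic-instrument
    quality control and unweighted risk-score construction, two-stage and
    summary-statistic causal estimators (inverse-variance weighted,
    MR-Egger, weighted median, MR-PRESSO) with pleiotropy diagnostics,
    residual-stratified non-linear Mendelian randomization with localized
    average causal effects, a continuity-constrained piecewise causal
    curve and formal non-linearity tests, plus a synthetic cohort
    generator that emulates the data structure the analysis assumes so
    every stage is testable without access to individual-level biobank
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr
Config/testthat/edition: 3
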