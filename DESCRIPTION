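Package: hdpscohort
Title: High-Dimensional Propensity Score Matched Cohort Studies on Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for new-user active-comparator cohort studies in
    longitudinal healthcare claims data, built around the high-dimensional
    propensity score (hdPS). Provides a synthetic claims-database generator
    with covariate-driven treatment channeling and known treatment effects,
    cohort extraction with flow-chart accounting, dispensing-based exposure
    algorithms (discontinuation, switch, retention, medication possession
    ratio), an age-weighted Charlson comorbidity index, empirical covariate
    generation across claims dimensions with Bross bias-formula
    prioritization, logistic propensity estimation, 1:1 caliper matching
    (greedy and optimal), standardized-difference balance diagnostics, and
    person-time incidence comparison via Kaplan-Meier, Cox, and
    (quasi-)Poisson models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
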