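Package: adipohtn
Title: Pooled Analysis of General and Abdominal Adiposity and Hypertension
Version: 0.1.0
Authors@R: person("NCD Surveillance", "Methods Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multi-study pooled analyses of general (body-mass
    index) and abdominal (waist-to-height ratio, WHtR) adiposity and their
    association with hypertension. Provides a synthetic multi-region,
    multi-study cohort generator with known ground truth; harmonisation of
    individual-level anthropometry and blood-pressure records; descriptive
    summaries (quantiles, within-region correlations, binned prevalence and
    case-density grids); a study-level random-intercept linear model of WHtR
    on BMI, age and region with delta-method confidence intervals for the
    regional BMI adjustment (the BMI shift a region would need to match a
    reference region's WHtR); and random-intercept logistic models of
    prevalent hypertension with C-statistics, continuous net reclassification
    improvement, and odds ratios per standard deviation of each adiposity
    metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
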