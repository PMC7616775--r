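# adipohtn

Pooled analysis of general (BMI) and abdominal (waist-to-height ratio)
adiposity and hypertension across multi-study, multi-region survey data —
as a tested, reusable R pipeline.

## Who this is for

Epidemiologists and biostatisticians running pooled analyses of
population-based surveys that measured height, weight, waist circumference,
repeated blood-pressure readings and antihypertensive medication use. Such
pooled individual-level datasets are almost never shareable, so the package
ships a synthetic cohort generator with known ground truth: every estimator
can be validated by parameter recovery instead of by access to restricted
data.

## What it computes

For each sex, with participants nested in studies nested in eight world
regions:

* **Harmonisation** — plausibility-range cleaning with a deterministic,
  auditable exclusion log; BMI = weight/height², WHtR = waist/height; mean
  BP discarding the first of repeated readings; hypertension = mean
  SBP ≥ 140 mmHg, mean DBP ≥ 90 mmHg, or current medication (treated =
  medicated regardless of BP; untreated = above threshold unmedicated).
* **Descriptives** — quantile summaries, within-region Pearson correlations
  of BMI and WHtR, BMI×WHtR prevalence grids (cells with ≤ 30 participants
  masked), hypertension case-density grids and cumulative case fractions.
* **Regional BMI adjustment** — from the study-level random-intercept model
  WHtR = μ + β·BMI + γ·age + δ_region + u_study + ε (REML, `lme4`), the
  quantity (δ_r − δ_ref)/β: how much lower a region's BMI would need to be
  to match the reference region's WHtR at equal age, with delta-method 95%
  CIs using the full fixed-effects covariance (plus an independent
  parametric-bootstrap CI).
* **Hypertension discrimination** — random-intercept logistic models of
  prevalent hypertension (null / BMI / WHtR / both, plus age, study-year
  bands, and region terms with interactions in pooled fits): C-statistics
  (rank method, ties = ½), continuous NRI versus the null model, and odds
  ratios per SD, unadjusted and mutually adjusted.

## Worked example

```r
library(adipohtn)

cfg <- pipeline_config(
  generator = generator_config(studies_per_region = 5, seed = 5),
  seed = 5
)
bundle <- run_pipeline(cfg, quiet = TRUE)

bundle$adjustments[bundle$adjustments$sex == "women",
                   c("region", "estimate", "ci_low", "ci_high")]
#>                                      region estimate ci_low ci_high
#>                         high-income western    0.000  0.000   0.000
#>                  central and eastern Europe   -1.114 -1.508  -0.719
#>  central Asia, Middle East and north Africa    2.250  1.854   2.645
#>     east and southeast Asia and the Pacific    1.035  0.641   1.429
#>             Latin America and the Caribbean    2.409  2.014   2.804
#>                                     Oceania   -0.902 -1.297  -0.507
#>                                  south Asia    2.663  2.269   3.057
#>                          sub-Saharan Africa    1.004  0.610   1.398
```

Reading: in this simulated world, women in the south-Asia analogue would
need a BMI 2.66 kg/m² lower (95% CI 2.27–3.06) to have the same mean WHtR
as the high-income-western reference at equal age; the generating truth for
that region is 2.80, inside the interval. Negative values mean the region's
WHtR is *below* the reference at equal BMI.

```r
bundle$discrimination[bundle$discrimination$region == "global" &
                      bundle$discrimination$sex == "women",
                      c("spec", "c_statistic", "c_null", "nri", "or_bmi", "or_whtr")]
#>  spec c_statistic c_null   nri or_bmi or_whtr
#>   bmi       0.743  0.679 0.520   2.02      NA
#>  whtr       0.738  0.679 0.500     NA    1.96
#>  both       0.744  0.679 0.535   1.61    1.28
```

Reading: BMI and WHtR discriminate hypertension almost identically
(C 0.743 vs 0.738 against a no-adiposity null of 0.679); adding both gives
only a marginal gain (0.744) — the same qualitative pattern pooled studies
report. ORs are per SD of each metric; in the `both` row they are mutually
adjusted and correspondingly attenuated.

`write_report_bundle(bundle, "report/")` writes every table as CSV plus
JSON exclusion log and provenance (config hash, seed, package version).

## Command line

```sh
Rscript inst/cli/adipohtn simulate --seed 3 --out cohort.csv
Rscript inst/cli/adipohtn clean cohort.csv clean.csv
Rscript inst/cli/adipohtn fit-whtr clean.csv --sex women
Rscript inst/cli/adipohtn run-all --seed 3 --out report/
```

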