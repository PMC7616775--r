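# Shared fixtures, all generated in code.

# small three-region world for fast structural tests; ... overrides defaults
small_config <- function(..., seed = 42L) {
  args <- list(
    regions = c("high-income western", "south Asia", "Oceania"),
    studies_per_region = 3,
    participants_per_study = 150,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# a noise-free world: WHtR exactly linear in BMI and age
noiseless_config <- function(..., seed = 7L) {
  small_config(
    study_intercept_sd = 0,
    whtr_residual_sd = 1e-7,
    bp_reading_sd = 0,
    first_reading_bias = 0,
    seed = seed,
    ...
  )
}

# build a harmonised-style table directly (bypassing the generator) for
# descriptive and discrimination unit tests
make_clean <- function(bmi, whtr, hypertension = NULL, region = "high-income western",
                       sex = "women", study_id = "s1", age = 40, year = 2010) {
  n <- length(bmi)
  data.frame(
    study_id = rep_len(study_id, n), region = rep_len(region, n),
    sex = rep_len(sex, n), age = rep_len(age, n),
    study_midyear = rep_len(year, n),
    bmi = bmi, whtr = whtr,
    hypertension = if (is.null(hypertension)) rep(NA, n) else rep_len(hypertension, n),
    stringsAsFactors = FALSE
  )
}

# a valid raw participant row for constructed cleaning fixtures
raw_row <- function(study_id = "s1", region = "high-income western",
                    sex = "women", age = 40, height = 165, weight = 68,
                    waist = 85, sbp = "125;120;122", dbp = "80;78;79",
                    meds = FALSE, year = 2010) {
  data.frame(study_id = study_id, region = region, sex = sex, age = age,
             height = height, weight = weight, waist = waist,
             sbp_readings = sbp, dbp_readings = dbp, on_medication = meds,
             study_midyear = year, stringsAsFactors = FALSE)
}

# O(n^2) pair-enumeration concordance oracle (independent of the rank method)
c_stat_brute <- function(p, y) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  cmp <- outer(cases, ctrls, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct up/down-counting NRI oracle
nri_brute <- function(p_new, p_old, y) {
  s <- 0
  for (i in seq_along(y)) {
    d <- sign(p_new[i] - p_old[i])
    s <- s + if (y[i] == 1) d / sum(y == 1) else -d / sum(y == 0)
  }
  s
}
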