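test_that("standardisation uses the sample SD and is idempotent", {
  tab <- make_clean(bmi = c(20, 30), whtr = c(0.4, 0.6))
  std <- standardize_adiposity(tab, "women")
  expect_equal(std$bmi_z, c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(attr(std, "scaling")$sd[["bmi"]], sd(c(20, 30)))

  # feeding z-scores back in returns them unchanged
  tab2 <- tab
  tab2$bmi <- std$bmi_z
  tab2$whtr <- std$whtr_z
  std2 <- standardize_adiposity(tab2, "women")
  expect_equal(std2$bmi_z, std$bmi_z, tolerance = 1e-12)
  expect_equal(std2$whtr_z, std$whtr_z, tolerance = 1e-12)

  expect_error(standardize_adiposity(make_clean(bmi = c(25, 25), whtr = c(0.4, 0.5)),
                                     "women"),
               class = "adipohtn_domain_error")
})

test_that("C-statistic handles separation, reversals and ties", {
  expect_equal(c_statistic(c(0.2, 0.6, 0.8), c(0, 0, 1)), 1.0)
  expect_equal(c_statistic(c(0.2, 0.6, 0.8), c(0, 1, 0)), 0.5)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), class = "adipohtn_domain_error")
})

test_that("rank-based C equals pair enumeration, and is monotone-invariant", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(10:300, 1)
    p <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE) else runif(n)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(c_statistic(p, y), c_stat_brute(p, y), tolerance = 1e-12)
    # any strictly increasing transform leaves C unchanged
    expect_equal(c_statistic(plogis(5 * p - 2), y), c_statistic(p, y),
                 tolerance = 1e-12)
  }
})

test_that("continuous NRI counts net up/down movements", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p_old <- rep(0.5, 8)
  p_new <- c(0.6, 0.6, 0.6, 0.4, 0.6, 0.6, 0.4, 0.4)  # 3/4 events up; non-events split
  expect_equal(continuous_nri(p_new, p_old, y), 0.5)
  expect_equal(continuous_nri(p_old, p_old, y), 0)
  expect_equal(continuous_nri(c(.9, .9, .9, .9, .1, .1, .1, .1), p_old, y), 2.0)
  expect_error(continuous_nri(p_new[-1], p_old, y), class = "adipohtn_input_error")
})

test_that("NRI is antisymmetric, bounded, and ignores exact ties", {
  set.seed(72)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    a <- round(runif(n), 2)  # rounding forces some exact ties
    b <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    nri <- continuous_nri(a, b, y)
    expect_equal(nri, -continuous_nri(b, a, y), tolerance = 1e-12)
    expect_equal(nri, nri_brute(a, b, y), tolerance = 1e-12)
    expect_true(nri >= -2 && nri <= 2)
  }
})

test_that("odds ratios exponentiate coefficients and their CIs", {
  nm <- c("(Intercept)", "bmi_z", "whtr_z", "age")
  V <- diag(c(0.01, 0.004, 0.0025, 1e-5))
  dimnames(V) <- list(nm, nm)
  fake <- structure(list(coefficients = setNames(c(-1.2, 0.5306, 0.3293, 0.05), nm),
                         vcov = V), class = "adipohtn_htn_fit")
  ors <- odds_ratios_per_sd(fake)
  expect_equal(ors$or[ors$term == "bmi"], 1.700, tolerance = 1e-3)
  expect_equal(ors$or[ors$term == "whtr"], 1.390, tolerance = 1e-3)
  expect_equal(ors$ci_low[ors$term == "bmi"],
               exp(0.5306 - 1.96 * sqrt(0.004)), tolerance = 1e-10)
  fake$coefficients["bmi_z"] <- 0
  expect_equal(odds_ratios_per_sd(fake)$or[1], 1.0)
})

test_that("mixed logistic fits recover generated adiposity effects", {
  cfg <- small_config(studies_per_region = 4, participants_per_study = 700,
                      bp_missing_fraction = 0)
  clean <- clean_cohort(generate_cohort(cfg, seed = 33))$clean
  std <- standardize_adiposity(clean, "women")
  fit <- fit_htn_model(std, "bmi")
  expect_true(fit$coefficients[["bmi_z"]] > 0)
  ors <- odds_ratios_per_sd(fit)
  expect_true(ors$or > 1.2 && ors$or < 3)

  # null world: adiposity coefficient within 3 SE of zero
  cfg0 <- small_config(studies_per_region = 4, participants_per_study = 700,
                       bp_missing_fraction = 0,
                       sbp_model = list(intercept = 112, bmi = 0, whtr = 0,
                                        age = 0.35, study_sd = 3, residual_sd = 11),
                       dbp_model = list(intercept = 69, bmi = 0, whtr = 0,
                                        age = 0.12, study_sd = 2, residual_sd = 8),
                       treatment_probability_model = c(intercept = -14, bmi = 0, sbp = 0.08))
  clean0 <- clean_cohort(generate_cohort(cfg0, seed = 34))$clean
  fit0 <- fit_htn_model(standardize_adiposity(clean0, "women"), "bmi")
  se0 <- sqrt(fit0$vcov["bmi_z", "bmi_z"])
  expect_lt(abs(fit0$coefficients[["bmi_z"]]), 3 * se0)
})

test_that("collinear adiposity metrics raise a rank-deficiency warning", {
  set.seed(41)
  n <- 400
  bmi <- rnorm(n, 27, 5)
  tab <- make_clean(bmi = bmi, whtr = 0.14 + 0.0125 * bmi,  # deterministic map
                    hypertension = rbinom(n, 1, plogis(-1 + 0.05 * (bmi - 27))) == 1,
                    study_id = rep(c("a", "b"), n / 2),
                    age = runif(n, 20, 64))
  std <- standardize_adiposity(tab, "women")
  expect_warning(fit_htn_model(std, "both", include_region = FALSE),
                 "rank-deficient")
})

test_that("the joint model's C-statistic is never materially below either single model", {
  cfg <- small_config(studies_per_region = 4, participants_per_study = 900,
                      bp_missing_fraction = 0)
  clean <- clean_cohort(generate_cohort(cfg, seed = 35))$clean
  std <- standardize_adiposity(clean, "men")
  fits <- lapply(c("bmi", "whtr", "both"), function(s) fit_htn_model(std, s))
  cs <- vapply(fits, function(f) c_statistic(f$p_conditional, f$outcomes), 0)
  expect_gte(cs[3], max(cs[1:2]) - 0.005)
})

test_that("exchangeable metrics yield matching single-metric C-statistics", {
  # both metrics load equally on one latent adiposity factor that drives risk
  set.seed(77)
  n <- 4000
  latent <- rnorm(n)
  bmi <- 27 + 5 * (sqrt(0.7) * latent + sqrt(0.3) * rnorm(n))
  whtr <- 0.55 + 0.07 * (sqrt(0.7) * latent + sqrt(0.3) * rnorm(n))
  y <- rbinom(n, 1, plogis(-1.4 + 0.8 * latent)) == 1
  tab <- make_clean(bmi = bmi, whtr = whtr, hypertension = y,
                    study_id = rep(c("a", "b", "c", "d"), each = n / 4),
                    age = runif(n, 20, 64))
  std <- standardize_adiposity(tab, "women")
  c_bmi <- c_statistic(fit_htn_model(std, "bmi")$p_conditional, std$hypertension)
  c_whtr <- c_statistic(fit_htn_model(std, "whtr")$p_conditional, std$hypertension)
  expect_lt(abs(c_bmi - c_whtr), 0.01)
})

test_that("discrimination report assembles all strata and skips small ones", {
  cfg <- small_config(studies_per_region = 4, participants_per_study = 400,
                      bp_missing_fraction = 0)
  clean <- clean_cohort(generate_cohort(cfg, seed = 37))$clean
  rep_tab <- discrimination_report(clean, sexes = "women", min_events = 30)
  expect_setequal(unique(rep_tab$region), c("global", cfg$regions))
  expect_setequal(unique(rep_tab$spec), c("bmi", "whtr", "both"))
  # per-SD ORs present where the metric is in the model
  expect_true(all(!is.na(rep_tab$or_bmi[rep_tab$spec %in% c("bmi", "both")])))
  expect_true(all(is.na(rep_tab$or_bmi[rep_tab$spec == "whtr"])))
  # C in [0,1], NRI in [-2,2]
  expect_true(all(rep_tab$c_statistic >= 0 & rep_tab$c_statistic <= 1))
  expect_true(all(rep_tab$nri >= -2 & rep_tab$nri <= 2))

  w <- capture_warnings(discrimination_report(clean, sexes = "women",
                                              min_events = 1e6))
  expect_true(all(grepl("skipped", w)) && length(w) > 0)
})
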