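test_that("noiseless data returns the generating coefficients", {
  cfg <- noiseless_config()
  clean <- clean_cohort(generate_cohort(cfg, seed = 2))$clean
  fit <- fit_whtr_model(clean, "women")
  expect_equal(fit$coefficients[["bmi"]], cfg$whtr_bmi_slope, tolerance = 1e-6)
  expect_equal(fit$coefficients[["age"]], cfg$whtr_age_slope, tolerance = 1e-6)
  expect_equal(fit$coefficients[["(Intercept)"]],
               unname(cfg$whtr_intercept_by_region["high-income western"]),
               tolerance = 1e-6)
  delta_sa <- cfg$whtr_intercept_by_region["south Asia"] -
    cfg$whtr_intercept_by_region["high-income western"]
  expect_equal(fit$coefficients[["region:south Asia"]], unname(delta_sa),
               tolerance = 1e-6)
})

test_that("fixed effects solve the GLS equations at the estimated components", {
  set.seed(51)
  n_per <- 30
  tab <- do.call(rbind, lapply(1:4, function(j) {
    region <- if (j <= 2) "high-income western" else "south Asia"
    bmi <- rnorm(n_per, 26, 4)
    age <- runif(n_per, 20, 64)
    u <- rnorm(1, 0, 0.006)
    make_clean(bmi = bmi,
               whtr = 0.14 + 0.0125 * bmi + 0.0008 * age + u + rnorm(n_per, 0, 0.03),
               region = region, study_id = paste0("st", j), age = age)
  }))
  fit <- fit_whtr_model(tab, "women")
  X <- cbind(1, tab$bmi, tab$age, as.integer(tab$region == "south Asia"))
  oracle <- gls_oracle(X, tab$whtr, tab$study_id, fit$sigma_u2, fit$sigma_e2)
  expect_equal(unname(fit$coefficients), oracle$coefficients, tolerance = 1e-7)
})

test_that("with no study heterogeneity the mixed fit collapses to OLS", {
  cfg <- small_config(study_intercept_sd = 0, seed = 3)
  clean <- clean_cohort(generate_cohort(cfg, seed = 3))$clean
  fit <- fit_whtr_model(clean, "men")
  sub <- clean[clean$sex == "men", ]
  sub$region <- factor(sub$region, levels = fit$regions)
  ols <- lm(whtr ~ bmi + age + region, data = sub)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-6)
})

test_that("slope recovery stays within 3 SE across seeds", {
  for (s in 1:5) {
    cfg <- small_config(studies_per_region = 5, participants_per_study = 400,
                        seed = s)
    clean <- clean_cohort(generate_cohort(cfg, seed = s))$clean
    fit <- fit_whtr_model(clean, "women")
    se <- sqrt(fit$vcov["bmi", "bmi"])
    expect_lt(abs(fit$coefficients[["bmi"]] - cfg$whtr_bmi_slope), 3 * se)
  }
})

test_that("adjusted mean WHtR is linear in the region offsets", {
  clean <- clean_cohort(generate_cohort(small_config(), seed = 4))$clean
  fit <- fit_whtr_model(clean, "women")
  a1 <- adjusted_mean_whtr(fit, at_bmi = 25, at_age = 40)
  a2 <- adjusted_mean_whtr(fit, at_bmi = 32, at_age = 55)
  d1 <- a1$estimate - a1$estimate[a1$region == "high-income western"]
  d2 <- a2$estimate - a2$estimate[a2$region == "high-income western"]
  expect_equal(d1, d2, tolerance = 1e-12)

  # at (0, 0) the reference value is the raw-scale intercept (extrapolation)
  expect_warning(a0 <- adjusted_mean_whtr(fit, at_bmi = 0, at_age = 0),
                 "extrapolat")
  expect_equal(a0$estimate[a0$region == "high-income western"],
               unname(fit$coefficients[["(Intercept)"]]))
})

test_that("adjusted-mean CI half-width matches a parametric bootstrap", {
  clean <- clean_cohort(generate_cohort(small_config(), seed = 19))$clean
  fit <- fit_whtr_model(clean, "women")
  am <- adjusted_mean_whtr(fit)
  r <- "south Asia"
  cvec <- setNames(numeric(length(fit$coefficients)), names(fit$coefficients))
  cvec["(Intercept)"] <- 1
  cvec["bmi"] <- fit$mean_bmi
  cvec["age"] <- fit$mean_age
  cvec[paste0("region:", r)] <- 1
  set.seed(99)
  draws <- matrix(rnorm(10000 * length(cvec)), 10000) %*% chol(fit$vcov)
  boot_sd <- sd(draws %*% cvec)
  half <- (am$ci_high - am$ci_low)[am$region == r] / 2
  expect_equal(half, 1.96 * boot_sd, tolerance = 0.03)
})

test_that("regional adjustment recovers the ratio and is re-referencing equivariant", {
  clean <- clean_cohort(generate_cohort(small_config(
    studies_per_region = 5, participants_per_study = 500), seed = 25))$clean
  fit <- fit_whtr_model(clean, "women", reference_region = "high-income western")
  adj <- regional_bmi_adjustment(fit)
  expect_equal(adj$estimate[adj$region == "high-income western"], 0)
  expect_equal(adj$se[adj$region == "high-income western"], 0)
  expect_true(all(adj$ci_low <= adj$estimate & adj$estimate <= adj$ci_high))

  # same fit, different reference: differences of estimates are preserved
  adj_oc <- regional_bmi_adjustment(fit, reference_region = "Oceania")
  shift <- adj$estimate[adj$region == "Oceania"]
  expect_equal(adj_oc$estimate, adj$estimate[match(adj_oc$region, adj$region)] - shift,
               tolerance = 1e-10)

  # refitting with another baseline leaves the adjustments unchanged
  fit2 <- fit_whtr_model(clean, "women", reference_region = "Oceania")
  adj2 <- regional_bmi_adjustment(fit2, reference_region = "high-income western")
  expect_equal(adj2$estimate[match(adj$region, adj2$region)], adj$estimate,
               tolerance = 1e-4)
})

test_that("a region with higher WHtR at equal BMI gets a positive adjustment", {
  cfg <- noiseless_config()
  clean <- clean_cohort(generate_cohort(cfg, seed = 6))$clean
  fit <- fit_whtr_model(clean, "women")
  adj <- regional_bmi_adjustment(fit)
  # south Asia's offset is above the reference: its BMI must be LOWER
  expect_gt(adj$estimate[adj$region == "south Asia"], 0)
  truth <- true_adjustments(cfg)
  expect_equal(adj$estimate[match(names(truth), adj$region)], unname(truth),
               tolerance = 1e-4)
})

test_that("delta arithmetic: d = 0.035, beta = 0.0125 gives 2.8 kg/m2", {
  # negligible-variance fit object exercises the ratio formula directly
  nm <- c("(Intercept)", "bmi", "age", "region:south Asia")
  V <- diag(1e-12, 4)
  dimnames(V) <- list(nm, nm)
  fake <- structure(list(
    coefficients = setNames(c(0.14, 0.0125, 0.0008, 0.035), nm),
    vcov = V,
    regions = c("high-income western", "south Asia"),
    reference_region = "high-income western", sex = "women"
  ), class = "adipohtn_whtr_fit")
  adj <- regional_bmi_adjustment(fake)
  expect_equal(adj$estimate[adj$region == "south Asia"], 2.8)
  fake$coefficients["region:south Asia"] <- -0.01
  adj2 <- regional_bmi_adjustment(fake)
  expect_equal(adj2$estimate[adj2$region == "south Asia"], -0.8)
})

test_that("an ill-determined BMI slope triggers the ratio precondition error", {
  cfg <- small_config(whtr_bmi_slope = 0, seed = 9)
  clean <- clean_cohort(generate_cohort(cfg, seed = 9))$clean
  fit <- fit_whtr_model(clean, "women")
  expect_error(regional_bmi_adjustment(fit), "bootstrap",
               class = "adipohtn_ratio_error")
})

test_that("single-study and single-region inputs are rejected", {
  clean <- clean_cohort(generate_cohort(small_config(), seed = 10))$clean
  one_study <- clean[clean$study_id == clean$study_id[1], ]
  expect_error(fit_whtr_model(one_study, "women"), class = "adipohtn_input_error")
  one_region <- clean[clean$region == "south Asia", ]
  expect_error(fit_whtr_model(one_region, "women"), class = "adipohtn_input_error")
})
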