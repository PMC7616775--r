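#' Configuration for the synthetic multi-study cohort generator
#'
#' Builds and validates the parameter set that defines a simulated world of
#' population surveys: per-region body-mass-index (BMI) distributions, a
#' linear waist-to-height-ratio (WHtR) structure with region offsets and
#' study-level random intercepts, blood-pressure (BP) models rising with BMI
#' and WHtR, repeated BP readings with a first-reading bias, treatment that
#' lowers measured BP, and configurable missingness and artifact rates.
#'
#' The generating model for abdominal adiposity is
#' \deqn{WHtR = \delta_r + \beta\,BMI + \gamma\,age + u_{study} + \epsilon}
#' with \eqn{u_{study} \sim N(0, \sigma_u^2)} shared by all participants of a
#' study and \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)} independent; waist
#' circumference is then \code{height * WHtR}. True (pre-measurement,
#' pre-treatment) systolic and diastolic BP follow analogous linear models in
#' BMI, WHtR and age with their own study intercepts.
#'
#' Defaults describe a plausible cross-regional world: log-normal BMI with
#' region- and sex-specific means (highest in Oceania, lowest in south Asia,
#' sub-Saharan Africa and east/southeast Asia), WHtR offsets largest for
#' south Asia, and a measured-BP model yielding roughly 15--25% hypertension
#' prevalence. They are illustrative, not calibrated to any real pooled
#' dataset; see the methods vignette for the reasoning behind each value.
#'
#' @param regions Character vector of region labels.
#' @param studies_per_region Number of studies simulated per region (>= 2 so
#'   the study random intercept is identifiable).
#' @param participants_per_study Participants drawn per study.
#' @param sex_ratio Proportion of women, in \[0, 1\].
#' @param age_range Two integers within \[20, 64\].
#' @param year_range Two integers within \[1990, 2023\] bounding study
#'   mid-years.
#' @param bmi_mean,bmi_sd Named matrices (region x sex) or single numbers,
#'   kg/m^2; BMI is drawn log-normal with these moments.
#' @param height_mean,height_sd Named vectors by sex (cm).
#' @param whtr_intercept_by_region Named vector of region offsets
#'   \eqn{\delta_r} (dimensionless).
#' @param whtr_bmi_slope \eqn{\beta}, WHtR per kg/m^2.
#' @param whtr_age_slope \eqn{\gamma}, WHtR per year of age.
#' @param study_intercept_sd \eqn{\sigma_u} of the WHtR study intercept.
#' @param whtr_residual_sd \eqn{\sigma_\epsilon} of the WHtR residual.
#' @param sbp_model,dbp_model Lists with elements \code{intercept} (mmHg),
#'   \code{bmi} (mmHg per kg/m^2), \code{whtr} (mmHg per WHtR unit),
#'   \code{age} (mmHg per year), \code{study_sd}, \code{residual_sd} (mmHg).
#' @param n_bp_readings Number of repeated BP readings taken (>= 1).
#' @param first_reading_bias mmHg added to the first reading only (white-coat
#'   effect).
#' @param bp_reading_sd Per-reading measurement noise, mmHg.
#' @param treatment_probability_model Logistic coefficients
#'   \code{c(intercept, bmi, sbp)} for the probability of being on
#'   antihypertensive medication given BMI and true SBP.
#' @param treatment_bp_reduction mmHg subtracted from measured SBP (and half
#'   of it from measured DBP) for treated participants.
#' @param bp_missing_fraction Fraction of participants with no BP readings
#'   and unknown medication status, in \[0, 1\].
#' @param artifact_rate Fraction of rows corrupted by
#'   \code{\link{inject_artifacts}} when the pipeline requests it.
#' @param seed Default integer seed used when \code{\link{generate_cohort}}
#'   is called without one.
#'
#' @return A validated list of class \code{"adipohtn_generator_config"}.
#' @seealso \code{\link{generate_cohort}}, \code{\link{true_adjustments}}
#' @export
generator_config <- function(regions = adipohtn_regions(),
                             studies_per_region = 10,
                             participants_per_study = 500,
                             sex_ratio = 0.5,
                             age_range = c(20, 64),
                             year_range = c(1990, 2023),
                             bmi_mean = NULL,
                             bmi_sd = NULL,
                             height_mean = c(women = 160, men = 172),
                             height_sd = c(women = 6.5, men = 7),
                             whtr_intercept_by_region = NULL,
                             whtr_bmi_slope = 0.0125,
                             whtr_age_slope = 0.0008,
                             study_intercept_sd = 0.005,
                             whtr_residual_sd = 0.035,
                             sbp_model = list(intercept = 85, bmi = 0.5, whtr = 25,
                                              age = 0.35, study_sd = 3, residual_sd = 11),
                             dbp_model = list(intercept = 55, bmi = 0.3, whtr = 12,
                                              age = 0.12, study_sd = 2, residual_sd = 8),
                             n_bp_readings = 3,
                             first_reading_bias = 5,
                             bp_reading_sd = 3,
                             treatment_probability_model = c(intercept = -14, bmi = 0.05, sbp = 0.08),
                             treatment_bp_reduction = 10,
                             bp_missing_fraction = 0.28,
                             artifact_rate = 0,
                             seed = 1L) {
  if (is.null(bmi_mean)) bmi_mean <- .default_bmi_moments(regions)$mean
  if (is.null(bmi_sd)) bmi_sd <- .default_bmi_moments(regions)$sd
  if (is.null(whtr_intercept_by_region)) {
    whtr_intercept_by_region <- .default_whtr_intercepts(regions)
  }
  bmi_mean <- .as_region_sex_matrix(bmi_mean, regions, "bmi_mean")
  bmi_sd <- .as_region_sex_matrix(bmi_sd, regions, "bmi_sd")

  cfg <- list(
    regions = regions,
    studies_per_region = as.integer(studies_per_region),
    participants_per_study = as.integer(participants_per_study),
    sex_ratio = sex_ratio,
    age_range = age_range,
    year_range = year_range,
    bmi_mean = bmi_mean,
    bmi_sd = bmi_sd,
    height_mean = height_mean,
    height_sd = height_sd,
    whtr_intercept_by_region = whtr_intercept_by_region,
    whtr_bmi_slope = whtr_bmi_slope,
    whtr_age_slope = whtr_age_slope,
    study_intercept_sd = study_intercept_sd,
    whtr_residual_sd = whtr_residual_sd,
    sbp_model = sbp_model,
    dbp_model = dbp_model,
    n_bp_readings = as.integer(n_bp_readings),
    first_reading_bias = first_reading_bias,
    bp_reading_sd = bp_reading_sd,
    treatment_probability_model = treatment_probability_model,
    treatment_bp_reduction = treatment_bp_reduction,
    bp_missing_fraction = bp_missing_fraction,
    artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "adipohtn_generator_config"
  validate_generator_config(cfg)
  cfg
}

# Illustrative regional BMI moments (kg/m^2): Oceania highest; south Asia,
# sub-Saharan Africa (men) and east/southeast Asia lowest; women wider.
.default_bmi_moments <- function(regions) {
  women_mean <- c(27.5, 27.0, 28.0, 28.5, 23.5, 25.0, 23.8, 30.5)
  men_mean   <- c(27.5, 27.8, 26.8, 27.0, 22.5, 22.5, 23.8, 29.5)
  women_sd   <- c(5.6, 6.0, 5.5, 5.8, 4.5, 5.5, 4.0, 6.5)
  men_sd     <- c(4.6, 4.8, 4.5, 4.7, 3.8, 3.7, 3.6, 5.5)
  canon <- adipohtn_regions()
  idx <- match(regions, canon)
  pick <- function(v) ifelse(is.na(idx), mean(v), v[pmax(idx, 1)])
  list(
    mean = cbind(women = pick(women_mean), men = pick(men_mean)),
    sd = cbind(women = pick(women_sd), men = pick(men_sd))
  )
}

# Region WHtR offsets delta_r, reference (high-income western) = 0.140.
# Ordering mimics the observed pattern for women: largest offset in south
# Asia, then Latin America and central Asia/Middle East/north Africa; lowest
# in central and eastern Europe. Every non-reference offset differs from the
# reference by at least 0.012 so all true BMI adjustments are ~1 kg/m^2 or
# more in magnitude (identifiable in recovery tests at realistic n).
.default_whtr_intercepts <- function(regions) {
  canon <- adipohtn_regions()
  base <- c(
    "central and eastern Europe" = 0.140 - 0.015,
    "high-income western" = 0.140,
    "Latin America and the Caribbean" = 0.140 + 0.0325,
    "central Asia, Middle East and north Africa" = 0.140 + 0.032,
    "south Asia" = 0.140 + 0.035,
    "sub-Saharan Africa" = 0.140 + 0.015,
    "east and southeast Asia and the Pacific" = 0.140 + 0.018,
    "Oceania" = 0.140 - 0.012
  )
  out <- base[match(regions, canon)]
  out[is.na(out)] <- 0.140
  names(out) <- regions
  out
}

.as_region_sex_matrix <- function(x, regions, what) {
  if (is.matrix(x)) {
    if (nrow(x) != length(regions) || ncol(x) != 2) {
      .abort(sprintf("config field '%s' must be a %d x 2 (region x sex) matrix",
                     what, length(regions)), "adipohtn_config_error")
    }
    colnames(x) <- .sexes
    rownames(x) <- regions
    return(x)
  }
  if (length(x) == 1) {
    m <- matrix(x, length(regions), 2, dimnames = list(regions, .sexes))
    return(m)
  }
  .abort(sprintf("config field '%s' must be scalar or region x sex matrix", what),
         "adipohtn_config_error")
}

#' Validate a generator configuration
#'
#' Checks the invariants of the stated simulation world and raises a
#' configuration error naming the offending field.
#'
#' @param cfg A \code{generator_config()} object.
#' @return The config, invisibly, if valid.
#' @export
validate_generator_config <- function(cfg) {
  bad <- function(field) {
    .abort(sprintf("invalid generator config: field '%s'", field),
           "adipohtn_config_error")
  }
  if (length(cfg$regions) < 1 || anyDuplicated(cfg$regions)) bad("regions")
  if (cfg$studies_per_region < 2) bad("studies_per_region")
  if (cfg$participants_per_study < 1) bad("participants_per_study")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) bad("sex_ratio")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2] ||
      cfg$age_range[1] < 20 || cfg$age_range[2] > 64) bad("age_range")
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2]) bad("year_range")
  if (any(cfg$bmi_sd < 0)) bad("bmi_sd")
  if (any(cfg$bmi_mean <= 0)) bad("bmi_mean")
  if (any(cfg$height_sd < 0)) bad("height_sd")
  if (cfg$study_intercept_sd < 0) bad("study_intercept_sd")
  if (cfg$whtr_residual_sd < 0) bad("whtr_residual_sd")
  for (m in c("sbp_model", "dbp_model")) {
    if (cfg[[m]]$study_sd < 0 || cfg[[m]]$residual_sd < 0) bad(m)
  }
  if (cfg$n_bp_readings < 1) bad("n_bp_readings")
  if (cfg$bp_reading_sd < 0) bad("bp_reading_sd")
  if (cfg$bp_missing_fraction < 0 || cfg$bp_missing_fraction > 1) bad("bp_missing_fraction")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) bad("artifact_rate")
  invisible(cfg)
}

# Deterministic per-study sub-stream seed: a fixed-stride counter keeps each
# study's draws independent of how many studies follow it.
.study_seed <- function(seed, counter) {
  (as.numeric(seed) + 104729 * counter) %% 2147483647
}

#' Generate a synthetic multi-region, multi-study cohort
#'
#' Draws one row per participant from the world described by \code{cfg}.
#' Each study has its own random intercept per outcome (WHtR, SBP, DBP) and
#' its own deterministic random sub-stream, so regenerating with the same
#' \code{(cfg, seed)} is byte-identical and adding studies does not perturb
#' earlier studies' draws.
#'
#' Measured BP readings are \code{true BP + reading noise}, with
#' \code{first_reading_bias} added to reading 1 only; participants on
#' medication have \code{treatment_bp_reduction} subtracted from measured SBP
#' (half from DBP). A fraction \code{bp_missing_fraction} of participants has
#' no BP readings and unknown medication status.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @param seed Integer seed; defaults to \code{cfg$seed}.
#' @return A data.frame of raw participant records (BP readings as
#'   semicolon-delimited strings), with attribute \code{"truth"} echoing the
#'   generating parameters.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  validate_generator_config(cfg)
  n_study <- cfg$studies_per_region
  pieces <- vector("list", length(cfg$regions) * n_study)
  counter <- 0L
  for (r in seq_along(cfg$regions)) {
    region <- cfg$regions[r]
    for (k in seq_len(n_study)) {
      counter <- counter + 1L
      pieces[[counter]] <- .generate_study(cfg, region, r, k,
                                           .study_seed(seed, counter))
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    whtr_bmi_slope = cfg$whtr_bmi_slope,
    whtr_age_slope = cfg$whtr_age_slope,
    whtr_intercept_by_region = cfg$whtr_intercept_by_region,
    study_intercept_sd = cfg$study_intercept_sd,
    seed = seed
  )
  out
}

.generate_study <- function(cfg, region, region_idx, study_idx, study_seed) {
  set.seed(study_seed)
  n <- cfg$participants_per_study
  study_id <- sprintf("%s_s%02d", gsub("[^A-Za-z]+", "_", region), study_idx)
  midyear <- sample(seq(cfg$year_range[1], cfg$year_range[2]), 1)

  u_whtr <- rnorm(1, 0, cfg$study_intercept_sd)
  u_sbp <- rnorm(1, 0, cfg$sbp_model$study_sd)
  u_dbp <- rnorm(1, 0, cfg$dbp_model$study_sd)

  sex <- ifelse(runif(n) < cfg$sex_ratio, "women", "men")
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  height <- rnorm(n, cfg$height_mean[sex], cfg$height_sd[sex])

  m <- cfg$bmi_mean[region, ][sex]
  s <- cfg$bmi_sd[region, ][sex]
  # log-normal with matched mean/sd (right-skewed, as observed for BMI)
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  bmi <- rlnorm(n, meanlog, sdlog)

  delta <- cfg$whtr_intercept_by_region[region]
  whtr <- delta + cfg$whtr_bmi_slope * bmi + cfg$whtr_age_slope * age +
    u_whtr + rnorm(n, 0, cfg$whtr_residual_sd)

  weight <- bmi * (height / 100)^2
  waist <- whtr * height

  lin_bp <- function(mdl, u) {
    mdl$intercept + mdl$bmi * bmi + mdl$whtr * whtr + mdl$age * age + u +
      rnorm(n, 0, mdl$residual_sd)
  }
  sbp_true <- lin_bp(cfg$sbp_model, u_sbp)
  dbp_true <- lin_bp(cfg$dbp_model, u_dbp)

  tp <- cfg$treatment_probability_model
  p_treat <- plogis(tp[["intercept"]] + tp[["bmi"]] * bmi + tp[["sbp"]] * sbp_true)
  treated <- runif(n) < p_treat

  k <- cfg$n_bp_readings
  bias <- c(cfg$first_reading_bias, rep(0, k - 1))
  red_sbp <- ifelse(treated, cfg$treatment_bp_reduction, 0)
  red_dbp <- red_sbp / 2
  sbp_mat <- matrix(rnorm(n * k, 0, cfg$bp_reading_sd), n, k) +
    outer(sbp_true - red_sbp, rep(1, k)) + matrix(bias, n, k, byrow = TRUE)
  dbp_mat <- matrix(rnorm(n * k, 0, cfg$bp_reading_sd), n, k) +
    outer(dbp_true - red_dbp, rep(1, k)) + matrix(bias / 2, n, k, byrow = TRUE)

  bp_missing <- runif(n) < cfg$bp_missing_fraction
  fmt <- function(mat) {
    cols <- lapply(seq_len(ncol(mat)), function(j) sprintf("%.6f", mat[, j]))
    do.call(paste, c(cols, sep = ";"))
  }
  sbp_readings <- ifelse(bp_missing, "", fmt(sbp_mat))
  dbp_readings <- ifelse(bp_missing, "", fmt(dbp_mat))
  on_medication <- ifelse(bp_missing, NA, treated)

  data.frame(
    study_id = study_id,
    region = region,
    sex = sex,
    age = age,
    height = height,
    weight = weight,
    waist = waist,
    sbp_readings = sbp_readings,
    dbp_readings = dbp_readings,
    on_medication = on_medication,
    study_midyear = midyear,
    stringsAsFactors = FALSE
  )
}

#' Corrupt a random subset of rows with implausible or missing values
#'
#' Test fixture for the cleaning stage: each selected row has one
#' anthropometric or age field replaced by a value far outside any plausible
#' range, or set missing. Only fields whose corruption must lead to exclusion
#' are touched (height, weight, waist, age), so the set of corrupted rows is
#' exactly the set a correct cleaner excludes.
#'
#' @param tab Raw cohort table.
#' @param artifact_rate Fraction of rows to corrupt, in \[0, 1\]; each row is
#'   corrupted independently with this probability.
#' @param seed Integer seed.
#' @return List with elements \code{table} (corrupted copy) and
#'   \code{corrupted} (integer row indices).
#' @export
inject_artifacts <- function(tab, artifact_rate, seed = 1L) {
  if (artifact_rate < 0 || artifact_rate > 1) {
    .abort("artifact_rate must be in [0, 1]", "adipohtn_config_error")
  }
  set.seed(seed)
  n <- nrow(tab)
  hit <- which(runif(n) < artifact_rate)
  if (length(hit) == 0) return(list(table = tab, corrupted = integer(0)))
  field <- sample(c("height", "weight", "waist", "age"), length(hit), replace = TRUE)
  bogus <- list(height = c(20, 400), weight = c(1, 900), waist = c(2, 700),
                age = c(5, 97))
  make_missing <- runif(length(hit)) < 0.25  # some artifacts are NAs, not values
  for (i in seq_along(hit)) {
    f <- field[i]
    tab[[f]][hit[i]] <- if (make_missing[i] && f != "age") NA_real_ else
      sample(bogus[[f]], 1)
  }
  list(table = tab, corrupted = hit)
}

#' Ground-truth regional BMI adjustments implied by a generator config
#'
#' The generating WHtR model gives each region offset \eqn{\delta_r}; the BMI
#' shift needed for region r to match the reference region's WHtR at equal
#' age is \eqn{(\delta_r - \delta_{ref}) / \beta}. These are the recovery
#' targets for \code{\link{regional_bmi_adjustment}}.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @param reference_region Region whose offset anchors the comparison.
#' @return Named numeric vector, kg/m^2, one element per region (reference = 0).
#' @export
true_adjustments <- function(cfg, reference_region = "high-income western") {
  if (cfg$whtr_bmi_slope == 0) {
    .abort("whtr_bmi_slope is 0: BMI adjustment is an undefined ratio",
           "adipohtn_ratio_error")
  }
  if (!reference_region %in% cfg$regions) {
    .abort("reference_region not in config regions", "adipohtn_config_error")
  }
  d <- cfg$whtr_intercept_by_region - cfg$whtr_intercept_by_region[reference_region]
  out <- d / cfg$whtr_bmi_slope
  names(out) <- cfg$regions
  out
}
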