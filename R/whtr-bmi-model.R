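#' Fit the mixed-effects linear model of WHtR on BMI, age and region
#'
#' Fits, by REML, the study-level random-intercept model
#' \deqn{WHtR_{ij} = \mu + \beta\,BMI_{ij} + \gamma\,age_{ij} + \delta_{r(j)}
#'   + u_j + \epsilon_{ij}}
#' for one sex, where \eqn{u_j} is a per-study intercept. BMI and age are
#' centred (at 25 kg/m^2 and 40 years) before fitting for conditioning;
#' coefficients and their covariance are reported back on the raw scale.
#'
#' @param clean Harmonised table with non-missing \code{bmi}, \code{whtr},
#'   \code{age}, \code{region}, \code{study_id}.
#' @param sex \code{"women"} or \code{"men"}.
#' @param reference_region Region coded as the model baseline.
#' @return Object of class \code{"adipohtn_whtr_fit"}: named coefficient
#'   vector (\code{(Intercept)}, \code{bmi}, \code{age}, one
#'   \code{region:<label>} per non-reference region), fixed-effects
#'   covariance matrix, variance components \code{sigma_u2}/\code{sigma_e2},
#'   sample metadata, and the underlying lme4 fit.
#' @export
fit_whtr_model <- function(clean, sex, reference_region = "high-income western") {
  sub <- clean[clean$sex == sex & !is.na(clean$bmi) & !is.na(clean$whtr) &
                 !is.na(clean$age), , drop = FALSE]
  if (nrow(sub) == 0) .abort("no rows for requested sex", "adipohtn_input_error")
  regions <- unique(sub$region)
  if (length(regions) < 2) .abort("need at least 2 regions", "adipohtn_input_error")
  if (length(unique(sub$study_id)) < 2) {
    .abort("need at least 2 studies: the study random intercept is unidentifiable",
           "adipohtn_input_error")
  }
  if (!reference_region %in% regions) {
    .abort("reference_region absent from data", "adipohtn_input_error")
  }
  sub$region <- stats::relevel(factor(sub$region,
                                      levels = c(reference_region,
                                                 sort(setdiff(regions, reference_region)))),
                               ref = reference_region)
  sub$bmi_c <- sub$bmi - 25
  sub$age_c <- sub$age - 40

  fit <- lme4::lmer(whtr ~ bmi_c + age_c + region + (1 | study_id),
                    data = sub, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages) == 0
  if (!isTRUE(conv) && !lme4::isSingular(fit)) {
    .abort(paste("mixed model did not converge:",
                 paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; ")),
           "adipohtn_convergence_error")
  }

  beta_c <- lme4::fixef(fit)
  V_c <- as.matrix(vcov(fit))
  # back-transform intercept to raw BMI/age scale: mu = mu_c - 25*beta - 40*gamma
  p <- length(beta_c)
  Tm <- diag(p)
  Tm[1, 2] <- -25
  Tm[1, 3] <- -40
  beta_raw <- drop(Tm %*% beta_c)
  V_raw <- Tm %*% V_c %*% t(Tm)
  nm <- names(beta_c)
  nm[2:3] <- c("bmi", "age")
  nm <- sub("^region", "region:", nm)
  names(beta_raw) <- nm
  dimnames(V_raw) <- list(nm, nm)

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "study_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]

  structure(list(
    coefficients = beta_raw,
    vcov = V_raw,
    sigma_u2 = sigma_u2,
    sigma_e2 = sigma_e2,
    n_obs = nrow(sub),
    n_studies = length(unique(sub$study_id)),
    regions = levels(sub$region),
    reference_region = reference_region,
    sex = sex,
    mean_bmi = mean(sub$bmi),
    mean_age = mean(sub$age),
    bmi_range = range(sub$bmi),
    converged = TRUE,
    singular = lme4::isSingular(fit),
    lme4_fit = fit
  ), class = "adipohtn_whtr_fit")
}

#' @export
print.adipohtn_whtr_fit <- function(x, ...) {
  cat(sprintf("WHtR ~ BMI + age + region mixed model (%s): %d obs, %d studies\n",
              x$sex, x$n_obs, x$n_studies))
  cat(sprintf("  beta(BMI) = %.5f per kg/m^2, gamma(age) = %.6f per year\n",
              x$coefficients["bmi"], x$coefficients["age"]))
  cat(sprintf("  sigma_u = %.5f, sigma_e = %.5f\n",
              sqrt(x$sigma_u2), sqrt(x$sigma_e2)))
  invisible(x)
}

# coefficient position of a region's offset; the baseline region maps to 0
.region_contrast <- function(fit, region) {
  v <- numeric(length(fit$coefficients))
  names(v) <- names(fit$coefficients)
  key <- paste0("region:", region)
  if (key %in% names(v)) v[key] <- 1
  else if (region != fit$regions[1]) {
    .abort(sprintf("region '%s' not in fitted model", region), "adipohtn_input_error")
  }
  v
}

#' Model-adjusted mean WHtR per region at a common BMI and age
#'
#' Evaluates \eqn{\mu + \beta\,BMI_0 + \gamma\,age_0 + \delta_r} for each
#' region, with a 95\% CI from the linear-combination variance
#' \eqn{c^\top \Sigma c} over the fixed-effects covariance. Defaults evaluate
#' at the sex-specific mean BMI and mean age of the analysis sample.
#'
#' @param fit An \code{\link{fit_whtr_model}} result.
#' @param at_bmi,at_age Evaluation point (kg/m^2, years).
#' @return data.frame: region, estimate, se, ci_low, ci_high.
#' @export
adjusted_mean_whtr <- function(fit, at_bmi = fit$mean_bmi, at_age = fit$mean_age) {
  if (at_bmi < fit$bmi_range[1] || at_bmi > fit$bmi_range[2]) {
    warning("at_bmi lies outside the fitted BMI range; extrapolating")
  }
  out <- do.call(rbind, lapply(fit$regions, function(r) {
    cvec <- .region_contrast(fit, r)
    cvec["(Intercept)"] <- 1
    cvec["bmi"] <- at_bmi
    cvec["age"] <- at_age
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    data.frame(region = r, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regional BMI adjustment with delta-method confidence intervals
#'
#' For each region the adjustment is \eqn{(\hat\delta_r - \hat\delta_{ref}) /
#' \hat\beta}: how much lower (positive values) or higher (negative) the
#' region's BMI would need to be to match the reference region's WHtR at
#' equal age. The variance follows from the first-order delta method using
#' the full fixed-effects covariance (gradient \eqn{1/\beta} on
#' \eqn{\delta_r}, \eqn{-1/\beta} on \eqn{\delta_{ref}}, \eqn{-d/\beta^2} on
#' \eqn{\beta}); 95\% CI = estimate +/- 1.96 se. Any region of the fit can be
#' the reference; results are equivariant to the model's internal baseline.
#'
#' @param fit An \code{\link{fit_whtr_model}} result.
#' @param reference_region Region the adjustments are relative to.
#' @return data.frame: region, sex, estimate, se, ci_low, ci_high,
#'   reference_region (the reference row has estimate 0 and zero width).
#' @export
regional_bmi_adjustment <- function(fit, reference_region = fit$reference_region) {
  beta <- fit$coefficients["bmi"]
  se_beta <- sqrt(fit$vcov["bmi", "bmi"])
  if (abs(beta) <= 5 * se_beta) {
    .abort("BMI slope is not bounded away from 0 (|beta| <= 5 se); the ratio CI is unreliable - use a bootstrap CI instead",
           "adipohtn_ratio_error")
  }
  c_ref <- .region_contrast(fit, reference_region)
  out <- do.call(rbind, lapply(fit$regions, function(r) {
    if (r == reference_region) {
      return(data.frame(region = r, sex = fit$sex, estimate = 0, se = 0,
                        ci_low = 0, ci_high = 0,
                        reference_region = reference_region,
                        stringsAsFactors = FALSE))
    }
    c_d <- .region_contrast(fit, r) - c_ref
    d <- sum(c_d * fit$coefficients)
    est <- d / beta
    grad <- c_d / beta
    grad["bmi"] <- grad["bmi"] - d / beta^2
    se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    data.frame(region = r, sex = fit$sex, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
               reference_region = reference_region, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Parametric-bootstrap CI for the regional BMI adjustment
#'
#' Independent check on the delta-method interval: draws coefficient vectors
#' from the multivariate normal \eqn{N(\hat\theta, \hat\Sigma)}, forms the
#' ratio for each draw, and takes percentile endpoints.
#'
#' @param fit An \code{\link{fit_whtr_model}} result.
#' @param reference_region Reference region.
#' @param n_draws Number of coefficient draws.
#' @param seed Integer seed.
#' @return data.frame: region, estimate (posterior-draw median), ci_low,
#'   ci_high.
#' @export
bootstrap_bmi_adjustment <- function(fit, reference_region = fit$reference_region,
                                     n_draws = 10000, seed = 1L) {
  set.seed(seed)
  p <- length(fit$coefficients)
  L <- chol(fit$vcov)
  draws <- matrix(rnorm(n_draws * p), n_draws, p) %*% L
  draws <- sweep(draws, 2, fit$coefficients, "+")
  colnames(draws) <- names(fit$coefficients)
  c_ref <- .region_contrast(fit, reference_region)
  out <- do.call(rbind, lapply(fit$regions, function(r) {
    if (r == reference_region) {
      return(data.frame(region = r, estimate = 0, ci_low = 0, ci_high = 0,
                        stringsAsFactors = FALSE))
    }
    c_d <- .region_contrast(fit, r) - c_ref
    ratio <- drop(draws %*% c_d) / draws[, "bmi"]
    qs <- quantile(ratio, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(region = r, estimate = qs[2], ci_low = qs[1], ci_high = qs[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generalised-least-squares oracle for the random-intercept linear model
#'
#' Direct matrix-algebra solution \eqn{(X^\top V^{-1} X)^{-1} X^\top V^{-1} y}
#' with \eqn{V = \sigma_\epsilon^2 I + \sigma_u^2 Z Z^\top}, used as an
#' independent check that the REML fit's fixed effects solve the GLS
#' equations at the estimated variance components. Dense; intended for small
#' fixtures only.
#'
#' @param X Fixed-effects design matrix.
#' @param y Response vector.
#' @param study Study identifier per row.
#' @param sigma_u2,sigma_e2 Variance components.
#' @return List with \code{coefficients} and \code{vcov}.
#' @export
gls_oracle <- function(X, y, study, sigma_u2, sigma_e2) {
  Z <- model.matrix(~ 0 + factor(study))
  V <- sigma_e2 * diag(length(y)) + sigma_u2 * Z %*% t(Z)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- solve(XtVi %*% X)
  list(coefficients = drop(A %*% XtVi %*% y), vcov = A)
}
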