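#' Z-score BMI and WHtR within the sex-specific analysis sample
#'
#' Odds ratios are reported per standard deviation of each adiposity metric,
#' so both are standardised on the pooled analysis sample of one sex; the
#' means and SDs used are recorded for reporting.
#'
#' @param clean Harmonised table.
#' @param sex \code{"women"} or \code{"men"}.
#' @return The sex subset with added \code{bmi_z} and \code{whtr_z} columns
#'   and attribute \code{"scaling"} (means and SDs, sample SD with n-1).
#' @export
standardize_adiposity <- function(clean, sex) {
  sub <- clean[clean$sex == sex & !is.na(clean$bmi) & !is.na(clean$whtr), ,
               drop = FALSE]
  if (nrow(sub) < 2) .abort("need at least 2 rows to standardise", "adipohtn_domain_error")
  sds <- c(bmi = sd(sub$bmi), whtr = sd(sub$whtr))
  if (any(sds == 0)) {
    .abort("zero standard deviation: cannot standardise a constant metric",
           "adipohtn_domain_error")
  }
  mns <- c(bmi = mean(sub$bmi), whtr = mean(sub$whtr))
  sub$bmi_z <- (sub$bmi - mns["bmi"]) / sds["bmi"]
  sub$whtr_z <- (sub$whtr - mns["whtr"]) / sds["whtr"]
  attr(sub, "scaling") <- list(mean = mns, sd = sds)
  sub
}

# Study mid-years grouped into the 5-year bands used for secular trends;
# reference band 1990-94. The final band spans 2020-23.
.year_band <- function(year) {
  breaks <- c(1990, 1995, 2000, 2005, 2010, 2015, 2020, 2024)
  labels <- c("1990-94", "1995-99", "2000-04", "2005-09", "2010-14",
              "2015-19", "2020-23")
  cut(year, breaks = breaks, labels = labels, right = FALSE,
      include.lowest = TRUE)
}

#' Fit a study-level random-intercept logistic model of hypertension
#'
#' Models prevalent hypertension on standardised adiposity terms (none, BMI,
#' WHtR, or both), linear age, 5-year study-year bands, and -- for pooled
#' fits -- region main effects with region x age and region x year
#' interactions. Estimation is by Laplace approximation (lme4::glmer); with
#' no real study heterogeneity the estimates coincide with plain logistic
#' regression.
#'
#' @param tab Output of \code{\link{standardize_adiposity}} (one sex) with
#'   non-missing \code{hypertension}.
#' @param adiposity_spec One of \code{"none"}, \code{"bmi"}, \code{"whtr"},
#'   \code{"both"}.
#' @param include_region Include region terms and interactions (TRUE for the
#'   pooled/global model; FALSE for single-region models).
#' @param reference_region Baseline region for pooled fits.
#' @param nAGQ Integration setting passed to lme4: 0 (default) estimates the
#'   fixed effects inside the penalised least-squares step, which is orders
#'   of magnitude faster for the large interaction designs used here and
#'   accurate for the modest study-level variances typical of BP surveys;
#'   1 requests the full Laplace approximation.
#' @return Object of class \code{"adipohtn_htn_fit"} with coefficients,
#'   covariance, study-intercept variance, per-participant fitted
#'   probabilities (conditional on the estimated study intercepts, and
#'   marginal fixed-effects-only), and the outcome vector.
#' @export
fit_htn_model <- function(tab, adiposity_spec = c("none", "bmi", "whtr", "both"),
                          include_region = TRUE,
                          reference_region = "high-income western",
                          nAGQ = 0) {
  adiposity_spec <- match.arg(adiposity_spec)
  sub <- tab[!is.na(tab$hypertension), , drop = FALSE]
  if (nrow(sub) == 0) .abort("no rows with known hypertension status", "adipohtn_input_error")
  if (length(unique(sub$study_id)) < 2) {
    .abort("need at least 2 studies for a study random intercept", "adipohtn_input_error")
  }
  sub$htn <- as.integer(sub$hypertension)
  sub$year_band <- droplevels(.year_band(sub$study_midyear))
  if (include_region) {
    regs <- unique(sub$region)
    ref <- if (reference_region %in% regs) reference_region else regs[1]
    sub$region <- factor(sub$region, levels = c(ref, sort(setdiff(regs, ref))))
  }

  adip <- switch(adiposity_spec, none = NULL, bmi = "bmi_z", whtr = "whtr_z",
                 both = c("bmi_z", "whtr_z"))
  rhs <- c(adip, "age")
  if (nlevels(sub$year_band) > 1) rhs <- c(rhs, "year_band")
  if (include_region && nlevels(sub$region) > 1) {
    rhs <- c(rhs, "region", "region:age")
    if (nlevels(sub$year_band) > 1) rhs <- c(rhs, "region:year_band")
  }
  fixed <- paste("htn ~", paste(rhs, collapse = " + "))

  # pre-check the main-effect design for rank deficiency (e.g. collinear
  # adiposity metrics) so the caller gets an interpretable warning;
  # interaction cells empty by design are dropped silently by lme4 instead
  mains <- setdiff(rhs, grep(":", rhs, value = TRUE))
  X0 <- model.matrix(as.formula(paste("htn ~", paste(mains, collapse = " + "))),
                     data = sub)
  if (qr(X0)$rank < ncol(X0)) {
    warning("fixed-effect design is rank-deficient (collinear covariates); coefficients are not uniquely identified")
  }

  fit <- suppressMessages(
    lme4::glmer(as.formula(paste(fixed, "+ (1 | study_id)")),
                data = sub, family = binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE)))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (fit@optinfo$conv$opt != 0) {
    .abort(paste("logistic mixed model did not converge:",
                 paste(msgs, collapse = "; ")), "adipohtn_convergence_error")
  }
  beta <- lme4::fixef(fit)
  if (any(abs(beta) > 20)) {
    .abort(paste("possible complete separation: extreme coefficient for",
                 paste(names(beta)[abs(beta) > 20], collapse = ", ")),
           "adipohtn_separation_error")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))

  structure(list(
    adiposity_spec = adiposity_spec,
    coefficients = beta,
    vcov = as.matrix(vcov(fit)),
    sigma_u2 = vc$vcov[vc$grp == "study_id"],
    p_conditional = fitted(fit),
    p_marginal = drop(plogis(lme4::getME(fit, "X") %*% beta)),
    outcomes = sub$htn,
    scaling = attr(tab, "scaling"),
    n_obs = nrow(sub),
    n_events = sum(sub$htn),
    include_region = include_region,
    lme4_fit = fit
  ), class = "adipohtn_htn_fit")
}

#' Odds ratios per SD of adiposity with 95\% confidence intervals
#'
#' @param fit An \code{\link{fit_htn_model}} result.
#' @return data.frame: term, log_or, se, or, ci_low, ci_high for each
#'   adiposity coefficient in the fit (empty for the null model).
#' @export
odds_ratios_per_sd <- function(fit) {
  terms <- intersect(c("bmi_z", "whtr_z"), names(fit$coefficients))
  out <- do.call(rbind, lapply(terms, function(tm) {
    b <- fit$coefficients[tm]
    se <- sqrt(fit$vcov[tm, tm])
    data.frame(term = sub("_z$", "", tm), log_or = unname(b), se = se,
               or = exp(unname(b)), ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(term = character(), log_or = numeric(),
                                      se = numeric(), or = numeric(),
                                      ci_low = numeric(), ci_high = numeric())
  rownames(out) <- NULL
  out
}

#' Concordance statistic for predicted probabilities
#'
#' Probability that a randomly chosen case has a higher predicted risk than
#' a randomly chosen non-case, ties counting one half. Computed by the
#' rank (Wilcoxon-Mann-Whitney) method in O(n log n); identical to explicit
#' enumeration over all case/non-case pairs.
#'
#' @param p Predicted probabilities (any monotone risk score works).
#' @param y Binary outcomes (0/1 or logical).
#' @return C-statistic in \[0, 1\].
#' @export
c_statistic <- function(p, y) {
  y <- as.integer(y)
  if (length(p) != length(y)) .abort("p and y lengths differ", "adipohtn_input_error")
  keep <- !is.na(p) & !is.na(y)
  p <- p[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    .abort("C-statistic needs at least one event and one non-event",
           "adipohtn_domain_error")
  }
  r <- rank(p)  # midranks handle ties as half-concordances
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Continuous net reclassification improvement
#'
#' \deqn{NRI = [P(\uparrow|case) - P(\downarrow|case)] +
#'   [P(\downarrow|noncase) - P(\uparrow|noncase)]}
#' where up/down means the new model's predicted risk is higher/lower than
#' the old model's; exact ties contribute to neither direction. Range
#' \[-2, 2\]; a model compared with itself scores exactly 0.
#'
#' @param p_new,p_old Aligned predicted-probability vectors.
#' @param y Binary outcomes.
#' @return Continuous NRI.
#' @export
continuous_nri <- function(p_new, p_old, y) {
  if (length(p_new) != length(p_old) || length(p_new) != length(y)) {
    .abort("p_new, p_old and y must have equal length", "adipohtn_input_error")
  }
  y <- as.integer(y)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    .abort("NRI needs at least one event and one non-event", "adipohtn_domain_error")
  }
  up <- p_new > p_old
  down <- p_new < p_old
  ev <- y == 1
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

#' Discrimination report: C-statistics, NRIs and ORs per stratum
#'
#' For the pooled sample ("global", with region terms) and each region
#' (region terms dropped), per sex, fits the four model specifications
#' (null, BMI, WHtR, both) and assembles C-statistics, continuous NRI of
#' each adiposity model against the null, and ORs per SD (unadjusted from
#' the single-metric fits; mutually adjusted from the joint fit).
#'
#' @param clean Harmonised table.
#' @param sexes Sexes to report.
#' @param min_events Strata with fewer hypertension events are skipped with
#'   a warning (default 50).
#' @param prediction One of \code{"conditional"} (fitted probabilities
#'   include the estimated study intercepts; default) or \code{"marginal"}
#'   (fixed effects only).
#' @return data.frame with one row per stratum x adiposity spec: region,
#'   sex, n, events, spec, c_statistic, c_null, nri, and OR columns (or_bmi,
#'   or_whtr with CIs; single-metric rows carry the unadjusted OR, the
#'   "both" row the mutually adjusted ones).
#' @export
discrimination_report <- function(clean, sexes = c("women", "men"),
                                  min_events = 50,
                                  prediction = c("conditional", "marginal")) {
  prediction <- match.arg(prediction)
  rows <- list()
  for (sx in sexes) {
    std <- standardize_adiposity(clean, sx)
    strata <- c("global", sort(unique(std$region)))
    for (stratum in strata) {
      tab <- if (stratum == "global") std else std[std$region == stratum, , drop = FALSE]
      tab <- tab[!is.na(tab$hypertension), , drop = FALSE]
      n_events <- sum(tab$hypertension)
      if (n_events < min_events || nrow(tab) - n_events < min_events) {
        warning(sprintf("stratum %s/%s skipped: %d events (< %d)",
                        stratum, sx, n_events, min_events))
        next
      }
      attr(tab, "scaling") <- attr(std, "scaling")
      fits <- lapply(c("none", "bmi", "whtr", "both"), function(spec) {
        fit_htn_model(tab, spec, include_region = (stratum == "global"))
      })
      names(fits) <- c("none", "bmi", "whtr", "both")
      pr <- function(f) if (prediction == "conditional") f$p_conditional else f$p_marginal
      y <- fits$none$outcomes
      c_null <- c_statistic(pr(fits$none), y)
      for (spec in c("bmi", "whtr", "both")) {
        f <- fits[[spec]]
        ors <- odds_ratios_per_sd(f)
        g <- function(term, col) {
          v <- ors[[col]][ors$term == term]
          if (length(v)) v else NA_real_
        }
        rows[[length(rows) + 1]] <- data.frame(
          region = stratum, sex = sx, n = f$n_obs, events = f$n_events,
          spec = spec,
          c_statistic = c_statistic(pr(f), y),
          c_null = c_null,
          nri = continuous_nri(pr(f), pr(fits$none), y),
          or_bmi = g("bmi", "or"), or_bmi_lo = g("bmi", "ci_low"),
          or_bmi_hi = g("bmi", "ci_high"),
          or_whtr = g("whtr", "or"), or_whtr_lo = g("whtr", "ci_low"),
          or_whtr_hi = g("whtr", "ci_high"),
          sd_bmi = unname(f$scaling$sd["bmi"]),
          sd_whtr = unname(f$scaling$sd["whtr"]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
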