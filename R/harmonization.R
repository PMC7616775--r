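#' Plausibility ranges and filters for cleaning raw records
#'
#' Default ranges follow standard surveillance-pooling practice (configurable;
#' boundary values are inclusive at both ends). Age and study-year windows
#' match the analysis frame of 20--64 years and 1990--2023.
#'
#' @param height_range,weight_range,waist_range,sbp_range,dbp_range,bmi_range,whtr_range
#'   Two-element numeric vectors (min, max) of plausible values.
#' @param age_range,year_range Analysis windows.
#' @return List of class \code{"adipohtn_cleaning_config"}.
#' @export
cleaning_config <- function(height_range = c(100, 250),
                            weight_range = c(12, 300),
                            waist_range = c(30, 300),
                            sbp_range = c(70, 270),
                            dbp_range = c(30, 150),
                            bmi_range = c(10, 80),
                            whtr_range = c(0.2, 1.5),
                            age_range = c(20, 64),
                            year_range = c(1990, 2023)) {
  cfg <- list(
    height_range = height_range, weight_range = weight_range,
    waist_range = waist_range, sbp_range = sbp_range, dbp_range = dbp_range,
    bmi_range = bmi_range, whtr_range = whtr_range,
    age_range = age_range, year_range = year_range
  )
  for (f in names(cfg)) {
    if (length(cfg[[f]]) != 2 || cfg[[f]][1] >= cfg[[f]][2]) {
      .abort(sprintf("cleaning config range '%s' must satisfy min < max", f),
             "adipohtn_config_error")
    }
  }
  class(cfg) <- "adipohtn_cleaning_config"
  cfg
}

#' Derive BMI and waist-to-height ratio from raw anthropometry
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param waist Waist circumference in cm.
#' @return List with numeric vectors \code{bmi} (kg/m^2, weight over squared
#'   height in metres) and \code{whtr} (waist over height, dimensionless).
#' @examples
#' derive_anthropometrics(175, 70, 87.5)  # bmi 22.86, whtr 0.5
#' @export
derive_anthropometrics <- function(height, weight, waist) {
  if (any(height <= 0 | weight <= 0 | waist <= 0, na.rm = TRUE)) {
    .abort("height, weight and waist must be positive", "adipohtn_domain_error")
  }
  list(bmi = weight / (height / 100)^2, whtr = waist / height)
}

#' Summarise repeated blood-pressure readings
#'
#' With two or more readings the first is discarded (it is systematically
#' elevated) and the remainder averaged; a single reading is used as-is; no
#' readings yields \code{NA}.
#'
#' @param readings Numeric vector of readings in measurement order, mmHg.
#' @return Mean mmHg, or \code{NA_real_} when no readings were taken.
#' @export
summarize_bp <- function(readings) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0) return(NA_real_)
  if (any(readings < 0)) {
    .abort("blood-pressure readings must be non-negative", "adipohtn_domain_error")
  }
  if (length(readings) == 1) return(readings)
  mean(readings[-1])
}

#' Classify hypertension status
#'
#' Treated hypertension is current antihypertensive medication use regardless
#' of blood pressure; untreated hypertension is mean SBP >= 140 mmHg or mean
#' DBP >= 90 mmHg without medication; status is missing when blood pressure
#' is absent and medication use is not known to be current.
#'
#' @param mean_sbp,mean_dbp Mean systolic/diastolic BP (mmHg), possibly NA.
#' @param on_medication Logical (TRUE/FALSE/NA).
#' @return Character vector with values \code{"treated"}, \code{"untreated"},
#'   \code{"none"}, or \code{NA}.
#' @export
classify_hypertension <- function(mean_sbp, mean_dbp, on_medication) {
  n <- max(length(mean_sbp), length(mean_dbp), length(on_medication))
  mean_sbp <- rep_len(mean_sbp, n)
  mean_dbp <- rep_len(mean_dbp, n)
  on_medication <- rep_len(on_medication, n)

  high <- (!is.na(mean_sbp) & mean_sbp >= 140) |
          (!is.na(mean_dbp) & mean_dbp >= 90)
  bp_present <- !is.na(mean_sbp) | !is.na(mean_dbp)

  out <- rep(NA_character_, n)
  out[bp_present & !high] <- "none"
  out[bp_present & high] <- "untreated"
  out[!is.na(on_medication) & on_medication] <- "treated"
  # meds explicitly FALSE but no BP: status unknowable -> stays NA
  out
}

# Fixed, documented rule order: a record failing several rules is attributed
# to the first.
.cleaning_rules <- c(
  "age_range", "year_range", "missing_anthropometry",
  "height_range", "weight_range", "waist_range",
  "bmi_range", "whtr_range", "sbp_range", "dbp_range"
)

.parse_readings <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

# vectorised variant: list of numeric reading vectors, one per row
.parse_readings_all <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, as.numeric)
}

#' Clean a raw cohort table and derive analysis variables
#'
#' Applies the age and study-year filters and the plausibility ranges of
#' \code{cfg} to every measured field, dropping and logging failures; rows
#' with missing BP are retained (hypertension status missing) so they remain
#' usable for adiposity-only analyses. Retained rows gain \code{bmi},
#' \code{whtr}, \code{mean_sbp}, \code{mean_dbp}, \code{hypertension} and
#' \code{htn_class}.
#'
#' @param tab Raw cohort table (see \code{\link{generate_cohort}}).
#' @param cfg A \code{\link{cleaning_config}}.
#' @return List with \code{clean} (the harmonised table) and \code{log}
#'   (an exclusion log: per-rule counts, per-row first-failing rule, and the
#'   excluded row indices).
#' @export
clean_cohort <- function(tab, cfg = cleaning_config()) {
  missing_cols <- setdiff(.raw_columns, names(tab))
  if (length(missing_cols) > 0) {
    .abort(paste("input table is missing columns:",
                 paste(missing_cols, collapse = ", ")), "adipohtn_input_error")
  }
  n <- nrow(tab)
  sbp_list <- .parse_readings_all(tab$sbp_readings)
  dbp_list <- .parse_readings_all(tab$dbp_readings)
  mean_bp <- function(lst) {
    len <- lengths(lst)
    out <- rep(NA_real_, n)
    out[len == 1] <- unlist(lst[len == 1])
    multi <- len >= 2
    # drop the biased first reading, average the rest
    out[multi] <- vapply(lst[multi], function(x) mean(x[-1]), 0)
    out
  }
  mean_sbp <- mean_bp(sbp_list)
  mean_dbp <- mean_bp(dbp_list)

  bmi <- tab$weight / (tab$height / 100)^2
  whtr <- tab$waist / tab$height

  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  bp_ok <- function(lst, r) {
    vapply(lst, function(x) length(x) == 0 || all(x >= r[1] & x <= r[2]), TRUE)
  }
  fail <- list(
    age_range = !in_range(tab$age, cfg$age_range),
    year_range = !in_range(tab$study_midyear, cfg$year_range),
    missing_anthropometry = is.na(tab$height) | is.na(tab$weight) | is.na(tab$waist),
    height_range = !is.na(tab$height) & !in_range(tab$height, cfg$height_range),
    weight_range = !is.na(tab$weight) & !in_range(tab$weight, cfg$weight_range),
    waist_range = !is.na(tab$waist) & !in_range(tab$waist, cfg$waist_range),
    bmi_range = !is.na(bmi) & !in_range(bmi, cfg$bmi_range),
    whtr_range = !is.na(whtr) & !in_range(whtr, cfg$whtr_range),
    sbp_range = !bp_ok(sbp_list, cfg$sbp_range),
    dbp_range = !bp_ok(dbp_list, cfg$dbp_range)
  )
  first_rule <- rep(NA_character_, n)
  for (rule in .cleaning_rules) {
    first_rule[is.na(first_rule) & fail[[rule]]] <- rule
  }
  keep <- is.na(first_rule)

  clean <- tab[keep, , drop = FALSE]
  clean$bmi <- bmi[keep]
  clean$whtr <- whtr[keep]
  clean$mean_sbp <- mean_sbp[keep]
  clean$mean_dbp <- mean_dbp[keep]
  clean$htn_class <- classify_hypertension(clean$mean_sbp, clean$mean_dbp,
                                           clean$on_medication)
  clean$hypertension <- ifelse(is.na(clean$htn_class), NA,
                               clean$htn_class %in% c("treated", "untreated"))
  rownames(clean) <- NULL

  counts <- table(factor(first_rule, levels = .cleaning_rules))
  log <- list(
    n_input = n,
    n_retained = sum(keep),
    n_excluded = sum(!keep),
    counts = as.list(counts),
    first_failing_rule = first_rule,
    excluded_rows = which(!keep)
  )
  class(log) <- "adipohtn_exclusion_log"
  list(clean = clean, log = log)
}

#' @export
print.adipohtn_exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusion log: %d input, %d retained, %d excluded\n",
              x$n_input, x$n_retained, x$n_excluded))
  nz <- Filter(function(v) v > 0, x$counts)
  for (rule in names(nz)) cat(sprintf("  %-22s %d\n", rule, nz[[rule]]))
  invisible(x)
}
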