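#' Read a cohort CSV
#'
#' Accepts two blood-pressure dialects: readings embedded as
#' semicolon-delimited strings in \code{sbp_readings}/\code{dbp_readings}
#' columns, or a long-format companion CSV with columns \code{row},
#' \code{reading}, \code{sbp}, \code{dbp} keyed to the main table's row
#' number. Schema is validated with per-column error messages.
#'
#' @param path Main CSV path.
#' @param bp_long_path Optional long-format BP companion CSV.
#' @return Raw cohort data.frame in the canonical column layout.
#' @export
read_cohort_csv <- function(path, bp_long_path = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(bp_long_path)) {
    long <- read.csv(bp_long_path, stringsAsFactors = FALSE)
    need <- setdiff(c("row", "reading", "sbp", "dbp"), names(long))
    if (length(need)) {
      .abort(paste("long BP file missing columns:", paste(need, collapse = ", ")),
             "adipohtn_input_error")
    }
    long <- long[order(long$row, long$reading), ]
    fmt <- function(col) {
      out <- rep("", nrow(tab))
      sp <- split(long[[col]], long$row)
      out[as.integer(names(sp))] <- vapply(sp, function(x)
        paste(sprintf("%.6f", x), collapse = ";"), "")
      out
    }
    tab$sbp_readings <- fmt("sbp")
    tab$dbp_readings <- fmt("dbp")
  }
  missing_cols <- setdiff(.raw_columns, names(tab))
  if (length(missing_cols)) {
    .abort(paste("cohort CSV missing columns:", paste(missing_cols, collapse = ", ")),
           "adipohtn_input_error")
  }
  for (col in c("age", "height", "weight", "waist", "study_midyear")) {
    if (!is.numeric(tab[[col]])) {
      .abort(sprintf("column '%s' must be numeric", col), "adipohtn_input_error")
    }
  }
  tab$sbp_readings <- as.character(tab$sbp_readings)
  tab$dbp_readings <- as.character(tab$dbp_readings)
  tab$sbp_readings[is.na(tab$sbp_readings)] <- ""
  tab$dbp_readings[is.na(tab$dbp_readings)] <- ""
  tab$on_medication <- as.logical(tab$on_medication)
  tab[, .raw_columns]
}

#' Write a cohort table to CSV
#'
#' @param tab Raw cohort table.
#' @param path Output path.
#' @param bp_format \code{"semicolon"} (default, single file) or
#'   \code{"long"} (BP readings in a companion file \code{<path>_bp.csv}).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(tab, path, bp_format = c("semicolon", "long")) {
  bp_format <- match.arg(bp_format)
  paths <- path
  if (bp_format == "long") {
    long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      s <- .parse_readings(tab$sbp_readings[i])
      d <- .parse_readings(tab$dbp_readings[i])
      if (length(s) == 0) return(NULL)
      data.frame(row = i, reading = seq_along(s), sbp = s, dbp = d)
    }))
    bp_path <- sub("\\.csv$", "_bp.csv", path)
    write.csv(long, bp_path, row.names = FALSE)
    tab$sbp_readings <- ""
    tab$dbp_readings <- ""
    paths <- c(path, bp_path)
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(paths)
}

#' Assemble a pipeline configuration
#'
#' @param generator A \code{\link{generator_config}} (used when no input CSV
#'   is given).
#' @param input_csv Optional path to an existing cohort CSV.
#' @param cleaning A \code{\link{cleaning_config}}.
#' @param grid_edges List with \code{bmi} and \code{whtr} edge vectors.
#' @param reference_region Reference for regional contrasts.
#' @param sexes Sexes to analyse.
#' @param prediction Prediction mode for discrimination metrics.
#' @param min_events Event floor per discrimination stratum.
#' @param seed Master seed.
#' @return List of class \code{"adipohtn_pipeline_config"}.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_csv = NULL,
                            cleaning = cleaning_config(),
                            grid_edges = default_grid_edges(),
                            reference_region = "high-income western",
                            sexes = c("women", "men"),
                            prediction = "conditional",
                            min_events = 50,
                            seed = 1L) {
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    .abort(sprintf("input_csv '%s' does not exist", input_csv), "adipohtn_config_error")
  }
  structure(list(generator = generator, input_csv = input_csv,
                 cleaning = cleaning, grid_edges = grid_edges,
                 reference_region = reference_region, sexes = sexes,
                 prediction = prediction, min_events = min_events,
                 seed = as.integer(seed)),
            class = "adipohtn_pipeline_config")
}

#' Run the full pipeline: simulate/read, clean, describe, fit, report
#'
#' Executes every stage in order and collects all tables into a report
#' bundle. Fully reproducible given the configuration and seed; each stage
#' logs one line with row counts in/out.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param quiet Suppress per-stage log lines.
#' @return List of class \code{"adipohtn_report_bundle"}: quantile
#'   summaries, correlation table, adjustment table, discrimination table,
#'   prevalence and case-density grids, exclusion log, true adjustments
#'   (when simulated), and a provenance block (config hash, seed, version).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  raw <- stage("simulate", {
    if (!is.null(config$input_csv)) read_cohort_csv(config$input_csv)
    else generate_cohort(config$generator, seed = config$seed)
  })
  say("simulate: %d rows", nrow(raw))

  if (is.null(config$input_csv) && config$generator$artifact_rate > 0) {
    raw <- inject_artifacts(raw, config$generator$artifact_rate,
                            seed = config$seed + 1L)$table
  }

  cleaned <- stage("clean", clean_cohort(raw, config$cleaning))
  say("clean: %d in, %d retained", cleaned$log$n_input, cleaned$log$n_retained)
  clean <- cleaned$clean

  quantiles <- stage("describe", {
    strata <- expand.grid(region = unique(clean$region), sex = .sexes,
                          metric = c("bmi", "whtr"), stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      v <- clean[[strata$metric[i]]][clean$region == strata$region[i] &
                                       clean$sex == strata$sex[i]]
      q <- distribution_quantiles(v)
      cbind(strata[i, ], as.data.frame(q), row.names = NULL)
    }))
  })
  correlations <- region_correlations(clean)
  say("describe: %d quantile rows, %d correlation strata",
      nrow(quantiles), nrow(correlations))

  grids <- list()
  for (sx in config$sexes) {
    sub <- clean[clean$sex == sx, ]
    grids[[sx]] <- list(
      prevalence = prevalence_grid(sub, config$grid_edges$bmi, config$grid_edges$whtr),
      case_density = case_density_grid(sub, config$grid_edges$bmi, config$grid_edges$whtr)
    )
  }

  adjustments <- stage("fit-whtr", do.call(rbind, lapply(config$sexes, function(sx) {
    fit <- fit_whtr_model(clean, sx, config$reference_region)
    regional_bmi_adjustment(fit)
  })))
  say("fit-whtr: %d adjustment rows", nrow(adjustments))

  discrimination <- stage("fit-htn",
    discrimination_report(clean, sexes = config$sexes,
                          min_events = config$min_events,
                          prediction = config$prediction))
  say("fit-htn: %d discrimination rows", nrow(discrimination))

  truth <- if (is.null(config$input_csv)) {
    data.frame(region = config$generator$regions,
               true_adjustment = unname(true_adjustments(config$generator,
                                                         config$reference_region)),
               stringsAsFactors = FALSE)
  } else NULL

  structure(list(
    quantiles = quantiles,
    correlations = correlations,
    adjustments = adjustments,
    discrimination = discrimination,
    grids = grids,
    exclusion_log = cleaned$log,
    truth = truth,
    provenance = list(
      config_hash = rlang::hash(config),
      seed = config$seed,
      package_version = as.character(packageVersion("adipohtn"))
    )
  ), class = "adipohtn_report_bundle")
}

#' Write every table of a report bundle to a directory
#'
#' Tables go to CSV, the exclusion log and provenance to JSON.
#'
#' @param bundle A \code{\link{run_pipeline}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$quantiles, file.path(dir, "quantiles.csv"), row.names = FALSE)
  write.csv(bundle$correlations, file.path(dir, "correlations.csv"), row.names = FALSE)
  write.csv(bundle$adjustments, file.path(dir, "adjustments.csv"), row.names = FALSE)
  write.csv(bundle$discrimination, file.path(dir, "discrimination.csv"), row.names = FALSE)
  for (sx in names(bundle$grids)) {
    write.csv(bundle$grids[[sx]]$prevalence,
              file.path(dir, paste0("prevalence_grid_", sx, ".csv")), row.names = FALSE)
    write.csv(bundle$grids[[sx]]$case_density,
              file.path(dir, paste0("case_density_grid_", sx, ".csv")), row.names = FALSE)
  }
  if (!is.null(bundle$truth)) {
    write.csv(bundle$truth, file.path(dir, "true_adjustments.csv"), row.names = FALSE)
  }
  log <- bundle$exclusion_log
  jsonlite::write_json(
    list(n_input = log$n_input, n_retained = log$n_retained,
         n_excluded = log$n_excluded, counts = log$counts),
    file.path(dir, "exclusion_log.json"), auto_unbox = TRUE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
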