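#' Five-number quantile summary of a distribution
#'
#' Returns the 2.5\%, 25\%, 50\%, 75\% and 97.5\% quantiles computed by
#' linear interpolation between order statistics at position
#' \eqn{h = (n-1)p + 1} (the common default rule), so implementations in
#' other languages agree bit-for-bit.
#'
#' @param values Numeric vector; NAs dropped.
#' @return List with \code{q2.5}, \code{q25}, \code{median}, \code{q75},
#'   \code{q97.5} and \code{n}.
#' @export
distribution_quantiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    .abort("distribution_quantiles needs at least one value", "adipohtn_domain_error")
  }
  q <- quantile(values, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                type = 7, names = FALSE)
  list(q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4], q97.5 = q[5],
       n = length(values))
}

#' Pearson correlation between BMI and WHtR per region and sex
#'
#' @param clean Harmonised table from \code{\link{clean_cohort}}.
#' @param min_n Minimum participants per stratum (default 3).
#' @return data.frame with columns region, sex, n, r. Strata with zero
#'   variance in either metric get \code{NA} with a warning.
#' @export
region_correlations <- function(clean, min_n = 3) {
  strata <- unique(clean[, c("region", "sex")])
  strata <- strata[order(strata$region, strata$sex), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- clean[clean$region == strata$region[i] & clean$sex == strata$sex[i], ]
    sub <- sub[!is.na(sub$bmi) & !is.na(sub$whtr), ]
    r <- NA_real_
    if (nrow(sub) >= min_n) {
      if (sd(sub$bmi) == 0 || sd(sub$whtr) == 0) {
        warning(sprintf("zero variance in stratum %s/%s: correlation undefined",
                        strata$region[i], strata$sex[i]))
      } else {
        r <- cor(sub$bmi, sub$whtr)
      }
    }
    data.frame(region = strata$region[i], sex = strata$sex[i],
               n = nrow(sub), r = r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Bin a value vector into [low, high) cells, last cell closed, values outside
# the edge range clipped into the end bins.
.bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

.check_edges <- function(edges, what) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    .abort(sprintf("%s bin edges must be strictly increasing", what),
           "adipohtn_config_error")
  }
}

#' Default BMI and WHtR grid edges
#'
#' BMI 15 to 50 kg/m^2 by 2.5; WHtR 0.30 to 1.00 by 0.05. Values outside are
#' clipped into the end bins.
#' @return List with \code{bmi} and \code{whtr} numeric vectors.
#' @export
default_grid_edges <- function() {
  list(bmi = seq(15, 50, by = 2.5), whtr = seq(0.30, 1.00, by = 0.05))
}

#' Hypertension prevalence on a BMI x WHtR grid
#'
#' Cross-tabulates participants with known hypertension status into
#' two-dimensional bins and computes per-cell prevalence. Cells with
#' \code{min_cell_count} or fewer participants are masked (prevalence set
#' missing) because their estimates are unstable.
#'
#' @param clean Harmonised table.
#' @param bmi_edges,whtr_edges Strictly increasing bin edges.
#' @param min_cell_count Mask cells with count <= this (default 30).
#' @return data.frame of class \code{"adipohtn_grid"}, one row per cell:
#'   bmi_lo, bmi_hi, whtr_lo, whtr_hi, count, n_hypertensive, prevalence,
#'   masked.
#' @export
prevalence_grid <- function(clean, bmi_edges = default_grid_edges()$bmi,
                            whtr_edges = default_grid_edges()$whtr,
                            min_cell_count = 30) {
  .check_edges(bmi_edges, "BMI")
  .check_edges(whtr_edges, "WHtR")
  sub <- clean[!is.na(clean$hypertension) & !is.na(clean$bmi) & !is.na(clean$whtr), ]
  .grid_summary(sub, sub$hypertension, bmi_edges, whtr_edges, min_cell_count)
}

.grid_summary <- function(sub, case, bmi_edges, whtr_edges, min_cell_count) {
  nb <- length(bmi_edges) - 1L
  nw <- length(whtr_edges) - 1L
  if (nrow(sub) > 0) {
    bi <- .bin_index(sub$bmi, bmi_edges)
    wi <- .bin_index(sub$whtr, whtr_edges)
    cell <- (wi - 1L) * nb + bi
    count <- tabulate(cell, nbins = nb * nw)
    cases <- tabulate(cell[case], nbins = nb * nw)
  } else {
    count <- cases <- integer(nb * nw)
  }
  grid <- expand.grid(bmi_bin = seq_len(nb), whtr_bin = seq_len(nw))
  out <- data.frame(
    bmi_lo = bmi_edges[grid$bmi_bin], bmi_hi = bmi_edges[grid$bmi_bin + 1L],
    whtr_lo = whtr_edges[grid$whtr_bin], whtr_hi = whtr_edges[grid$whtr_bin + 1L],
    count = count, n_hypertensive = cases
  )
  out$masked <- out$count <= min_cell_count
  out$prevalence <- ifelse(out$masked | out$count == 0, NA_real_,
                           out$n_hypertensive / out$count)
  attr(out, "bmi_edges") <- bmi_edges
  attr(out, "whtr_edges") <- whtr_edges
  attr(out, "n_graded") <- nrow(sub)
  class(out) <- c("adipohtn_grid", "data.frame")
  out
}

#' Density of hypertensive participants on a BMI x WHtR grid
#'
#' Like \code{\link{prevalence_grid}} but counts only participants with
#' hypertension (the case mass), and additionally reports the medians of BMI
#' and WHtR among cases and among all graded participants (the reference
#' lines of the case-density display).
#'
#' @inheritParams prevalence_grid
#' @return An \code{"adipohtn_grid"} whose \code{count} column is the number
#'   of cases per cell, with attribute \code{"medians"}.
#' @export
case_density_grid <- function(clean, bmi_edges = default_grid_edges()$bmi,
                              whtr_edges = default_grid_edges()$whtr,
                              min_cell_count = 0) {
  .check_edges(bmi_edges, "BMI")
  .check_edges(whtr_edges, "WHtR")
  graded <- clean[!is.na(clean$hypertension) & !is.na(clean$bmi) & !is.na(clean$whtr), ]
  cases <- graded[graded$hypertension, ]
  out <- .grid_summary(cases, rep(TRUE, nrow(cases)), bmi_edges, whtr_edges,
                       min_cell_count)
  med <- function(x) if (length(x)) median(x) else NA_real_
  attr(out, "medians") <- list(
    bmi_cases = med(cases$bmi), whtr_cases = med(cases$whtr),
    bmi_all = med(graded$bmi), whtr_all = med(graded$whtr)
  )
  out
}

#' Fraction of hypertension cases at or below BMI and WHtR cut-offs
#'
#' Quantifies how much of the case burden sits in the low-adiposity range
#' (most cases arise where most people are, not where individual risk is
#' highest).
#'
#' @param clean Harmonised table.
#' @param bmi_max,whtr_max Inclusive upper cut-offs.
#' @return Proportion of hypertensive participants with BMI <= bmi_max and
#'   WHtR <= whtr_max.
#' @export
cumulative_case_fraction <- function(clean, bmi_max, whtr_max) {
  cases <- clean[!is.na(clean$hypertension) & clean$hypertension &
                   !is.na(clean$bmi) & !is.na(clean$whtr), ]
  if (nrow(cases) == 0) {
    .abort("no hypertensive participants in stratum", "adipohtn_domain_error")
  }
  mean(cases$bmi <= bmi_max & cases$whtr <= whtr_max)
}
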