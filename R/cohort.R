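#' Pipeline configuration
#'
#' Bundles the knobs of the per-donor pipeline: calibration prior and grid,
#' point rule, and (for raw AMS input) the blank model and precision policy.
#'
#' @param prior_range calibration prior interval; `NULL` = full curve domain.
#' @param grid_step calibration grid step, years.
#' @param point_rule `"highest-mass"` or `"nearest"` (see [calibrate()]).
#' @param reference_year reference for rule `"nearest"`; `NA` means use each
#'   donor's documented birth year (the validation-study setting).
#' @param blank a [blank_model()] applied to raw records, or `NULL` to skip
#'   blank correction.
#' @param precision a [precision_policy()] for raw-record sigmas.
#' @param weighted if `TRUE`, [regress_cohort()] weights by
#'   `1/predicted_sigma^2`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(prior_range = NULL, grid_step = 0.05,
                            point_rule = "highest-mass",
                            reference_year = NULL, blank = NULL,
                            precision = precision_policy(),
                            weighted = FALSE) {
  structure(list(prior_range = prior_range, grid_step = grid_step,
                 point_rule = point_rule, reference_year = reference_year,
                 blank = blank, precision = precision, weighted = weighted),
            class = "pipeline_config")
}

# Reduce one raw AMS row to a blank-corrected f14c_value.
reduce_raw_donor <- function(row, config) {
  v <- fraction_modern(row, policy = config$precision)
  v <- background_correct(v, f14c_value(row$machine_background, 0))
  if (!is.null(config$blank))
    v <- blank_mass_correct(v, config$blank, row$carbon_mass_total)
  v
}

#' Run the per-donor dating pipeline
#'
#' For each donor: reduce the raw AMS record if present (fraction modern →
#' background correction → blank mass balance), calibrate the fraction
#' modern against the atmospheric curve, and record the point estimate and
#' its uncertainty (half-width of the 68.3% HPD of the selected mode). A
#' failing stage attaches its message to that donor's `flags` and the
#' pipeline continues; failed donors carry `NA` predictions and are excluded
#' from the regression downstream. Donors are processed independently, so
#' the result does not depend on row order.
#'
#' @param donors data frame with `donor_id`, `birth_year`, `collection_year`
#'   and either reduced columns `f14c`, `sigma` or the raw AMS columns of
#'   [ams_record()].
#' @param curve an [atm_curve()].
#' @param config a [pipeline_config()].
#' @return The input data frame with columns `predicted_year`,
#'   `predicted_sigma`, `point_rule`, `flags` appended.
#' @export
predict_birth_years <- function(donors, curve, config = pipeline_config()) {
  stopifnot(is.data.frame(donors), inherits(curve, "atm_curve"))
  raw_mode <- "ratio_sample" %in% names(donors)
  if (!raw_mode && !all(c("f14c", "sigma") %in% names(donors)))
    stop("donors need either reduced columns (f14c, sigma) or raw AMS columns")
  n <- nrow(donors)
  out <- donors
  out$predicted_year <- NA_real_
  out$predicted_sigma <- NA_real_
  out$point_rule <- NA_character_
  out$flags <- ""
  for (i in seq_len(n)) {
    res <- tryCatch({
      v <- if (raw_mode) reduce_raw_donor(donors[i, , drop = FALSE], config)
           else f14c_value(donors$f14c[i], donors$sigma[i])
      ref <- config$reference_year
      rule <- config$point_rule
      if (identical(rule, "nearest") && (is.null(ref) || is.na(ref)))
        ref <- donors$birth_year[i]
      cal <- calibrate(v, curve, prior_range = config$prior_range,
                       grid_step = config$grid_step, point_rule = rule,
                       reference_year = ref)
      list(year = cal$point_estimate, sigma = cal$point_sigma,
           rule = cal$point_rule,
           flags = paste(c(if (v$flag) "clipped", cal$flags), collapse = ";"))
    }, error = function(e) list(year = NA_real_, sigma = NA_real_,
                                rule = NA_character_,
                                flags = conditionMessage(e)))
    out$predicted_year[i] <- res$year
    out$predicted_sigma[i] <- res$sigma
    out$point_rule[i] <- res$rule
    out$flags[i] <- res$flags
  }
  out
}

#' Predicted-versus-actual birth-year regression
#'
#' Ordinary least squares of the calibrated (predicted) year of birth on the
#' documented year of birth across the cohort — the validation regression:
#' with no turnover and an accurate pipeline the slope is 1 and the
#' intercept 0. Unweighted by default; `weighted = TRUE` uses weights
#' `1/predicted_sigma^2`.
#'
#' @param donors output of [predict_birth_years()] (donors with `NA`
#'   predictions are dropped; at least 3 must remain).
#' @param weighted logical.
#' @return An object of class `cohort_regression` with fields `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r_squared`, `n`, `excluded`,
#'   and the underlying `lm` fit in `$fit`.
#' @examples
#' d <- data.frame(birth_year = c(1960, 1970, 1980, 1990),
#'                 predicted_year = c(1961, 1969, 1980, 1990))
#' regress_cohort(d)  # slope 0.98, intercept 39.5, R^2 0.9963
#' @export
regress_cohort <- function(donors, weighted = FALSE) {
  ok <- is.finite(donors$predicted_year) & is.finite(donors$birth_year)
  d <- donors[ok, , drop = FALSE]
  if (nrow(d) < 3)
    stop("regression error: need at least 3 donors with valid predictions")
  if (var(d$birth_year) == 0)
    stop("degenerate error: zero variance in birth years")
  w <- if (weighted) {
    if (any(!is.finite(d$predicted_sigma)) || any(d$predicted_sigma <= 0))
      stop("weighted regression needs positive predicted_sigma for all donors")
    1 / d$predicted_sigma^2
  } else NULL
  fit <- lm(predicted_year ~ birth_year, data = d, weights = w)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 n = nrow(d), excluded = sum(!ok),
                 weighted = weighted, fit = fit),
            class = "cohort_regression")
}

#' @export
print.cohort_regression <- function(x, ...) {
  cat(sprintf("Predicted vs actual birth year (%sOLS, n = %d%s)\n",
              if (x$weighted) "weighted " else "", x$n,
              if (x$excluded) sprintf(", %d excluded", x$excluded) else ""))
  cat(sprintf("  slope     %.4f +/- %.4f\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.1f +/- %.1f yr\n", x$intercept, x$intercept_se))
  cat(sprintf("  R^2       %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.cohort_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Read a donor table
#'
#' Reduced mode: header `donor_id,birth_year,collection_year,f14c,sigma`.
#' Raw mode: the [ams_record()] header plus `birth_year,collection_year`
#' (`sample_id` doubles as `donor_id` if the latter is absent). Comma- or
#' tab-delimited; `#` comments ignored.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_donors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- read.table(text = lines, header = TRUE, sep = sep,
                   strip.white = TRUE, stringsAsFactors = FALSE)
  if (!"donor_id" %in% names(df) && "sample_id" %in% names(df))
    df$donor_id <- df$sample_id
  need <- c("donor_id", "birth_year", "collection_year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("parse error in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  if (!"ratio_sample" %in% names(df) &&
      !all(c("f14c", "sigma") %in% names(df)))
    stop(sprintf("parse error in '%s': need f14c,sigma or raw AMS columns", path))
  if (any(df$collection_year <= df$birth_year))
    stop("collection_year must exceed birth_year for every donor")
  df
}

#' Write a donor table
#'
#' Years are rounded to 0.01 in files (full precision is kept in memory);
#' the write is deterministic, so identical inputs yield byte-identical
#' files.
#'
#' @param donors a donor data frame (possibly with predictions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_donors <- function(donors, path) {
  out <- donors
  for (col in intersect(c("birth_year", "collection_year", "predicted_year",
                          "predicted_sigma"), names(out)))
    out[[col]] <- round(out[[col]], 2)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
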