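#' Fraction-modern value with one-sigma uncertainty
#'
#' The basic currency of the reduction chain: a fraction-modern (F14C)
#' measurement together with its one-sigma uncertainty and a logical flag
#' raised when a correction had to clip the value at zero. All fields are
#' parallel vectors, so a single object can hold a whole batch.
#'
#' @param f14c fraction modern, dimensionless, `>= 0`.
#' @param sigma one-sigma uncertainty, dimensionless, `>= 0`.
#' @param flag logical; `TRUE` marks values that were clipped or otherwise
#'   degraded by a correction step.
#' @return An object of class `f14c_value` with fields `f14c`, `sigma`, `flag`.
#' @examples
#' f14c_value(1.30, 0.0065)
#' @export
f14c_value <- function(f14c, sigma = 0, flag = FALSE) {
  if (!is.numeric(f14c) || !is.numeric(sigma))
    stop("f14c and sigma must be numeric")
  n <- max(length(f14c), length(sigma))
  f14c  <- rep_len(as.numeric(f14c), n)
  sigma <- rep_len(as.numeric(sigma), n)
  flag  <- rep_len(as.logical(flag), n)
  if (any(!is.finite(f14c)) || any(f14c < 0))
    stop("fraction modern must be finite and >= 0")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and >= 0")
  structure(list(f14c = f14c, sigma = sigma, flag = flag),
            class = "f14c_value")
}

#' @export
format.f14c_value <- function(x, ...) {
  sprintf("%.5f +/- %.5f%s", x$f14c, x$sigma, ifelse(x$flag, " [flagged]", ""))
}

#' @export
print.f14c_value <- function(x, ...) {
  cat("F14C value(s):\n")
  cat(paste0("  ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.f14c_value <- function(x) length(x$f14c)

#' delta-13C value (permil vs VPDB) with one-sigma uncertainty
#'
#' @param delta13c permil deviation of 13C/12C from VPDB; must exceed −1000
#'   (the physical lower bound of the delta scale).
#' @param sigma one-sigma uncertainty, permil, `>= 0`.
#' @return An object of class `delta_value`.
#' @export
delta_value <- function(delta13c, sigma = 0) {
  n <- max(length(delta13c), length(sigma))
  delta13c <- rep_len(as.numeric(delta13c), n)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(!is.finite(delta13c)) || any(delta13c <= -1000))
    stop("delta13c must be finite and > -1000 permil")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and >= 0")
  structure(list(delta13c = delta13c, sigma = sigma), class = "delta_value")
}

#' @export
print.delta_value <- function(x, ...) {
  cat(sprintf("  %+.3f +/- %.3f permil (VPDB)\n", x$delta13c, x$sigma), sep = "")
  invisible(x)
}

#' Procedural-blank model
#'
#' Describes the carbon introduced by reagents and handling (the procedural
#' blank): its fraction modern and mass, both with one-sigma uncertainties.
#' Blanks from the solvent-extraction protocol typically carry 10–20 μg of
#' carbon against 70–120 μg sample targets, so the correction is material.
#'
#' @param f14c_blank fraction modern of the blank carbon.
#' @param sigma_f_blank its one-sigma uncertainty.
#' @param mass_blank blank carbon mass, μg.
#' @param sigma_mass_blank its one-sigma uncertainty, μg.
#' @param mass_range plausibility range for `mass_blank`, μg (default 0–50).
#' @return An object of class `blank_model`.
#' @export
blank_model <- function(f14c_blank, sigma_f_blank = 0, mass_blank,
                        sigma_mass_blank = 0, mass_range = c(0, 50)) {
  vals <- c(f14c_blank, sigma_f_blank, mass_blank, sigma_mass_blank)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all blank_model fields must be finite and >= 0")
  if (mass_blank < mass_range[1] || mass_blank > mass_range[2])
    stop(sprintf("mass_blank %.1f ug outside plausibility range [%g, %g]",
                 mass_blank, mass_range[1], mass_range[2]))
  structure(list(f14c_blank = f14c_blank, sigma_f_blank = sigma_f_blank,
                 mass_blank = mass_blank, sigma_mass_blank = sigma_mass_blank),
            class = "blank_model")
}

#' Raw AMS measurement records
#'
#' One row per graphite target: the sample isotope ratio, the ratio measured
#' on the normalization standard (oxalic acid I, fractionation-normalized to
#' −19 permil), the sample's delta-13C, the total carbon mass combusted, a
#' batch label, and the machine background expressed in fraction-modern
#' equivalents (from radiocarbon-free graphite).
#'
#' @param sample_id character id(s).
#' @param ratio_sample measured 14C/12C (or 14C/13C) ratio of the sample.
#' @param ratio_standard same ratio on the normalization standard
#'   (already fractionation-normalized to −19 permil).
#' @param delta13c sample delta-13C, permil vs VPDB.
#' @param carbon_mass_total total carbon combusted, μg.
#' @param batch_id batch label (samples were processed ~5–6 per batch on
#'   different CO2 handling lines).
#' @param machine_background fraction-modern equivalent of the instrument
#'   background.
#' @return A `data.frame` with class `ams_records`.
#' @export
ams_record <- function(sample_id, ratio_sample, ratio_standard, delta13c,
                       carbon_mass_total, batch_id = "B1",
                       machine_background = 0) {
  df <- data.frame(sample_id = as.character(sample_id),
                   ratio_sample = as.numeric(ratio_sample),
                   ratio_standard = as.numeric(ratio_standard),
                   delta13c = as.numeric(delta13c),
                   carbon_mass_total = as.numeric(carbon_mass_total),
                   batch_id = as.character(batch_id),
                   machine_background = as.numeric(machine_background),
                   stringsAsFactors = FALSE)
  validate_ams_records(df)
  class(df) <- c("ams_records", "data.frame")
  df
}

validate_ams_records <- function(df) {
  if (any(!is.finite(df$ratio_sample)) || any(df$ratio_sample <= 0) ||
      any(!is.finite(df$ratio_standard)) || any(df$ratio_standard <= 0))
    stop("reduction error: isotope ratios must be positive")
  if (any(df$carbon_mass_total <= 0))
    stop("carbon_mass_total must be > 0")
  if (any(df$machine_background < 0))
    stop("machine_background must be >= 0")
  if (any(df$delta13c <= -1000) || any(df$delta13c >= 1e5))
    stop("delta13c outside (-1000, 100000) permil")
  invisible(df)
}
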