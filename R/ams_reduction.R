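#' Per-batch measurement precision policy
#'
#' AMS counting precision depends on target size: better than 0.5% (relative)
#' for targets above ~50 μg of carbon, substantially worse below. Batches
#' processed on different CO2 handling lines can carry multipliers.
#'
#' @param rel relative one-sigma for masses at/above `mass_threshold`
#'   (default 0.005, i.e. 0.5%).
#' @param rel_small relative one-sigma below the threshold (default 0.02).
#' @param mass_threshold carbon mass threshold, μg (default 50).
#' @return A list of class `precision_policy`.
#' @export
precision_policy <- function(rel = 0.005, rel_small = 0.02,
                             mass_threshold = 50) {
  stopifnot(rel > 0, rel_small > 0, mass_threshold > 0)
  structure(list(rel = rel, rel_small = rel_small,
                 mass_threshold = mass_threshold),
            class = "precision_policy")
}

#' Measurement sigma from the precision policy
#'
#' @param f14c fraction modern value(s).
#' @param carbon_mass_total carbon mass(es), μg, `> 0`.
#' @param policy a [precision_policy()].
#' @param multiplier per-batch precision multiplier(s).
#' @return numeric sigma(s), `f14c * rel * multiplier`.
#' @examples
#' batch_precision(1.300, 100)  # 0.0065
#' @export
batch_precision <- function(f14c, carbon_mass_total,
                            policy = precision_policy(), multiplier = 1) {
  if (any(!is.finite(carbon_mass_total)) || any(carbon_mass_total <= 0))
    stop("parameter error: carbon mass must be positive")
  rel <- ifelse(carbon_mass_total >= policy$mass_threshold,
                policy$rel, policy$rel_small)
  f14c * rel * multiplier
}

#' Reduce a raw AMS record to fraction modern
#'
#' Applies the internationally standard reduction: the sample ratio is
#' fractionation-normalized to delta-13C = −25 permil via the multiplicative
#' factor `(0.975 / (1 + delta13c/1000))^2`, then divided by 0.95 times the
#' oxalic-acid-I standard ratio (itself normalized to −19 permil), the
#' definition of fraction modern. The uncertainty comes from counting
#' statistics when ratio sigmas are supplied, otherwise from the per-batch
#' precision policy and the target's carbon mass.
#'
#' @param rec an [ams_record()] data frame (vectorized over rows).
#' @param policy a [precision_policy()] for the fallback sigma.
#' @param multiplier per-batch precision multiplier(s).
#' @param sigma_ratio_sample,sigma_ratio_standard optional counting-statistics
#'   sigmas of the two ratios; when both are given the relative errors are
#'   combined in quadrature instead of using the policy.
#' @return An [f14c_value()], one element per record.
#' @export
fraction_modern <- function(rec, policy = precision_policy(), multiplier = 1,
                            sigma_ratio_sample = NULL,
                            sigma_ratio_standard = NULL) {
  validate_ams_records(rec)
  frac <- (0.975 / (1 + rec$delta13c / 1000))^2
  f <- rec$ratio_sample * frac / (0.95 * rec$ratio_standard)
  if (!is.null(sigma_ratio_sample) && !is.null(sigma_ratio_standard)) {
    sig <- f * sqrt((sigma_ratio_sample / rec$ratio_sample)^2 +
                    (sigma_ratio_standard / rec$ratio_standard)^2)
  } else {
    sig <- batch_precision(f, rec$carbon_mass_total, policy, multiplier)
  }
  f14c_value(f, sig)
}

#' Instrument-background correction
#'
#' Subtracts the machine background (measured on radiocarbon-free commercial
#' and geological graphite) from the raw fraction modern; linear subtraction
#' is adequate for backgrounds far below the sample signal. Sigmas combine in
#' quadrature. A background exceeding the raw value clips the result to zero
#' and raises the flag.
#'
#' @param raw an [f14c_value()] before background correction.
#' @param background an [f14c_value()] holding the background level.
#' @return A corrected [f14c_value()].
#' @export
background_correct <- function(raw, background) {
  stopifnot(inherits(raw, "f14c_value"), inherits(background, "f14c_value"))
  f <- raw$f14c - background$f14c
  s <- sqrt(raw$sigma^2 + background$sigma^2)
  clip <- f < 0
  if (any(clip)) {
    warning("background exceeds raw value; corrected F14C clipped at 0")
    f[clip] <- 0
  }
  f14c_value(f, s, flag = raw$flag | background$flag | clip)
}

#' Procedural-blank mass-balance correction
#'
#' The measured target is a two-component mixture of sample and blank carbon:
#' `f_meas * m_total = f_sample * (m_total - m_blank) + f_blank * m_blank`.
#' Solving for the sample,
#' `f_sample = (f_meas * m_total - f_blank * m_blank) / (m_total - m_blank)`.
#' The one-sigma is propagated to first order over `(f_meas, f_blank,
#' m_blank)`; the total mass is treated as exactly known (it is measured
#' manometrically to much better precision than the blank mass).
#'
#' @param measured an [f14c_value()] for the combusted target.
#' @param blank a [blank_model()].
#' @param carbon_mass_total total carbon mass of the target, μg; must exceed
#'   the blank mass.
#' @return A blank-corrected [f14c_value()].
#' @examples
#' blank_mass_correct(f14c_value(1.200, 0.006),
#'                    blank_model(0.60, 0.01, 15, 2), 100)  # 1.30588
#' @export
blank_mass_correct <- function(measured, blank, carbon_mass_total) {
  stopifnot(inherits(measured, "f14c_value"), inherits(blank, "blank_model"))
  M <- carbon_mass_total
  mb <- blank$mass_blank
  if (any(!is.finite(M)) || any(M <= mb))
    stop("correction error: blank mass >= total carbon mass (blank dominates)")
  ms <- M - mb
  f <- (measured$f14c * M - blank$f14c_blank * mb) / ms
  v <- (M / ms)^2 * measured$sigma^2 +
       (mb / ms)^2 * blank$sigma_f_blank^2 +
       (M * (measured$f14c - blank$f14c_blank) / ms^2)^2 *
         blank$sigma_mass_blank^2
  clip <- f < 0
  if (any(clip)) {
    warning("blank correction produced negative F14C; clipped at 0")
    f[clip] <- 0
  }
  f14c_value(f, sqrt(v), flag = measured$flag | clip)
}

#' Read raw AMS records from a delimited text file
#'
#' Header `sample_id,ratio_sample,ratio_standard,delta13c,carbon_mass_total,`
#' `batch_id,machine_background`, comma- or tab-delimited, `#` comments
#' ignored. Extra columns (e.g. `birth_year`, `collection_year` for cohort
#' use) are carried through.
#'
#' @param path file path.
#' @return An `ams_records` data frame.
#' @export
read_ams_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- read.table(text = lines, header = TRUE, sep = sep,
                   strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "ratio_sample", "ratio_standard", "delta13c",
            "carbon_mass_total", "batch_id", "machine_background")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("parse error in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  validate_ams_records(df)
  class(df) <- c("ams_records", "data.frame")
  df
}
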