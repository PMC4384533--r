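#' Specification of a synthetic donor cohort
#'
#' Defines the study conditions emulated by the generators: 23 donors born
#' mid-year between 1948 and 1993 (documented birth years map to YYYY.5),
#' collected in 2010, no turnover, per-batch measurement noise of about
#' 0.5–2% in fraction modern, procedural blanks of 10–20 μg against targets
#' of 70–120 μg, processed roughly 5–6 samples per batch.
#'
#' @param n_donors number of donors.
#' @param birth_year_range decimal-year interval of birth dates.
#' @param collection_year decimal year of tissue collection.
#' @param turnover_k true exchange rate, per year.
#' @param noise_sigma_f14c measurement noise sd in fraction modern (before
#'   batch multipliers).
#' @param blank a [blank_model()] describing the procedural blank F14C.
#' @param blank_mass_range blank carbon mass range drawn per target, μg.
#' @param sample_mass_range total target carbon mass range, μg.
#' @param batch_size donors per batch.
#' @param batch_multipliers per-batch precision multipliers, recycled over
#'   batches.
#' @param seed integer RNG seed; recorded in the truth sidecar.
#' @param spacing `"even"` (deterministic grid over the range) or
#'   `"uniform"` (random draws).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 23,
                        birth_year_range = c(1948.5, 1993.5),
                        collection_year = 2010.0,
                        turnover_k = 0,
                        noise_sigma_f14c = 0.01,
                        blank = blank_model(0.60, 0.01, 15, 2),
                        blank_mass_range = c(10, 20),
                        sample_mass_range = c(70, 120),
                        batch_size = 5,
                        batch_multipliers = 1,
                        seed = 1L,
                        spacing = c("even", "uniform")) {
  spacing <- match.arg(spacing)
  if (n_donors < 1) stop("n_donors must be >= 1")
  if (noise_sigma_f14c < 0) stop("noise_sigma_f14c must be >= 0")
  if (turnover_k < 0) stop("turnover_k must be >= 0")
  if (diff(birth_year_range) < 0) stop("invalid birth_year_range")
  if (min(sample_mass_range) <= max(blank_mass_range))
    stop("sample masses must exceed blank masses")
  structure(list(n_donors = as.integer(n_donors),
                 birth_year_range = birth_year_range,
                 collection_year = collection_year,
                 turnover_k = turnover_k,
                 noise_sigma_f14c = noise_sigma_f14c,
                 blank = blank, blank_mass_range = blank_mass_range,
                 sample_mass_range = sample_mass_range,
                 batch_size = as.integer(batch_size),
                 batch_multipliers = batch_multipliers,
                 seed = as.integer(seed), spacing = spacing),
            class = "cohort_spec")
}

check_spec_domain <- function(spec, curve) {
  dom <- range(curve$year)
  if (spec$birth_year_range[1] < dom[1] || spec$birth_year_range[2] > dom[2])
    stop("parameter error: birth_year_range outside curve domain")
  if (spec$turnover_k > 0 &&
      (spec$collection_year > dom[2] || spec$collection_year < dom[1]))
    stop("parameter error: collection_year outside curve domain (needed for k > 0)")
}

spec_batches <- function(spec) {
  n <- spec$n_donors
  batch <- rep(seq_len(ceiling(n / spec$batch_size)),
               each = spec$batch_size)[seq_len(n)]
  mult <- rep_len(spec$batch_multipliers, max(batch))[batch]
  list(batch = batch, mult = mult)
}

spec_births <- function(spec) {
  r <- spec$birth_year_range
  if (spec$spacing == "even") {
    if (spec$n_donors == 1) mean(r)
    else seq(r[1], r[2], length.out = spec$n_donors)
  } else sort(runif(spec$n_donors, r[1], r[2]))
}

#' Generate a synthetic donor cohort (reduced mode)
#'
#' Draws birth years per the spec, sets each true fraction modern to
#' [predict_f14c()] under the spec's turnover rate, and adds Gaussian
#' measurement noise scaled by the donor's batch multiplier. Deterministic
#' under a fixed seed; the caller's RNG state is left untouched. Ground
#' truth goes to a separate sidecar data frame so blinded testing is
#' possible.
#'
#' @param spec a [cohort_spec()].
#' @param curve an [atm_curve()] covering the spec's birth range (and the
#'   collection year if `turnover_k > 0`).
#' @return A list of class `synthetic_cohort` with `donors` (columns
#'   `donor_id`, `birth_year`, `collection_year`, `f14c`, `sigma`,
#'   `batch_id`) and `truth` (adds `f14c_true`, `turnover_k`,
#'   `noise_sigma_f14c`, `seed`).
#' @export
generate_cohort <- function(spec, curve) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(curve, "atm_curve"))
  check_spec_domain(spec, curve)
  with_seed(spec$seed, {
    births <- spec_births(spec)
    bt <- spec_batches(spec)
    truth <- vapply(births, function(b)
      predict_f14c(turnover_model(spec$turnover_k, b, spec$collection_year),
                   curve), numeric(1))
    sig <- spec$noise_sigma_f14c * bt$mult
    obs <- truth + rnorm(spec$n_donors, 0, sig)
    obs <- pmax(obs, 0)
    donors <- data.frame(
      donor_id = sprintf("D%03d", seq_len(spec$n_donors)),
      birth_year = births, collection_year = spec$collection_year,
      f14c = obs, sigma = sig,
      batch_id = sprintf("B%02d", bt$batch),
      stringsAsFactors = FALSE)
    truth_df <- data.frame(
      donor_id = donors$donor_id, birth_year = births,
      f14c_true = truth, turnover_k = spec$turnover_k,
      noise_sigma_f14c = spec$noise_sigma_f14c, seed = spec$seed,
      stringsAsFactors = FALSE)
    structure(list(donors = donors, truth = truth_df),
              class = "synthetic_cohort")
  })
}

#' Generate synthetic raw AMS records
#'
#' Inverts the whole reduction chain so that running the records through
#' [fraction_modern()], [background_correct()] and [blank_mass_correct()]
#' recovers the generated values to machine precision: the true sample
#' fraction modern (plus measurement noise) is forward-mixed with a drawn
#' procedural blank, a machine background is added, and isotope ratios are
#' emitted consistent with the delta-13C fractionation normalization at
#' delta-13C drawn near −22.7 permil.
#'
#' @param spec a [cohort_spec()].
#' @param curve an [atm_curve()].
#' @return A list of class `synthetic_raw` with `records` (an
#'   [ams_record()] frame plus `birth_year`, `collection_year`), `blanks`
#'   (per-target [blank_model()]s in a list), and `truth` (adds the mixed
#'   and true values and the draws).
#' @export
generate_raw_records <- function(spec, curve) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(curve, "atm_curve"))
  check_spec_domain(spec, curve)
  with_seed(spec$seed, {
    n <- spec$n_donors
    births <- spec_births(spec)
    bt <- spec_batches(spec)
    f_true <- vapply(births, function(b)
      predict_f14c(turnover_model(spec$turnover_k, b, spec$collection_year),
                   curve), numeric(1))
    f_sample <- pmax(f_true + rnorm(n, 0, spec$noise_sigma_f14c * bt$mult), 0)
    mb <- runif(n, spec$blank_mass_range[1], spec$blank_mass_range[2])
    M <- runif(n, spec$sample_mass_range[1], spec$sample_mass_range[2])
    f_meas <- (f_sample * (M - mb) + spec$blank$f14c_blank * mb) / M
    bg <- runif(n, 0.001, 0.003)
    delta <- rnorm(n, -22.7, 0.5)
    frac <- (0.975 / (1 + delta / 1000))^2
    ratio_standard <- rep(1.0, n)            # normalized units
    ratio_sample <- (f_meas + bg) * 0.95 * ratio_standard / frac
    records <- data.frame(
      sample_id = sprintf("D%03d", seq_len(n)),
      ratio_sample = ratio_sample, ratio_standard = ratio_standard,
      delta13c = delta, carbon_mass_total = M,
      batch_id = sprintf("B%02d", bt$batch), machine_background = bg,
      birth_year = births, collection_year = spec$collection_year,
      stringsAsFactors = FALSE)
    validate_ams_records(records)
    class(records) <- c("ams_records", "data.frame")
    blanks <- lapply(mb, function(m)
      blank_model(spec$blank$f14c_blank, spec$blank$sigma_f_blank, m,
                  spec$blank$sigma_mass_blank))
    truth <- data.frame(
      donor_id = records$sample_id, birth_year = births,
      f14c_true = f_true, f14c_sample = f_sample, f14c_measured = f_meas,
      mass_blank = mb, carbon_mass_total = M, machine_background = bg,
      delta13c = delta, turnover_k = spec$turnover_k, seed = spec$seed,
      stringsAsFactors = FALSE)
    structure(list(records = records, blanks = blanks, truth = truth),
              class = "synthetic_raw")
  })
}

#' Write a synthetic cohort (donors plus truth sidecar)
#'
#' Emits `<prefix>_donors.csv` and `<prefix>_truth.csv`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  p1 <- paste0(prefix, "_donors.csv")
  p2 <- paste0(prefix, "_truth.csv")
  write_donors(cohort$donors, p1)
  write.table(cohort$truth, p2, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
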