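test_that("noiseless no-turnover cohorts sit exactly on the curve", {
  crv <- fixture_curve()
  co <- generate_cohort(cohort_spec(noise_sigma_f14c = 0, seed = 3), crv)
  expect_equal(co$donors$f14c, curve_at(crv, co$donors$birth_year)$f14c)
  expect_equal(co$donors$f14c, co$truth$f14c_true)
  expect_equal(nrow(co$donors), 23)
  # births evenly spaced across the documented range, mid-year convention
  expect_equal(range(co$donors$birth_year), c(1948.5, 1993.5))
})

test_that("generation is deterministic under a fixed seed and leaves RNG alone", {
  crv <- fixture_curve()
  a <- generate_cohort(cohort_spec(seed = 42), crv)
  b <- generate_cohort(cohort_spec(seed = 42), crv)
  expect_identical(a, b)
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generate_cohort(cohort_spec(seed = 7), crv))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
  expect_error(generate_cohort(cohort_spec(birth_year_range = c(1890, 1990)),
                               crv), "parameter error")
  expect_error(generate_cohort(cohort_spec(turnover_k = 0.1), crv),
               "parameter error")
})

test_that("generator noise has the declared spread and no bias", {
  crv <- fixture_curve()
  co <- generate_cohort(cohort_spec(n_donors = 10000, noise_sigma_f14c = 0.01,
                                    seed = 8), crv)
  resid <- co$donors$f14c - co$truth$f14c_true
  expect_gt(sd(resid), 0.0097)
  expect_lt(sd(resid), 0.0103)
  expect_lt(abs(mean(resid)), 3 * 0.01 / sqrt(10000))
})

test_that("per-batch multipliers scale the recorded sigmas", {
  crv <- fixture_curve()
  co <- generate_cohort(cohort_spec(n_donors = 10, batch_size = 5,
                                    batch_multipliers = c(1, 2),
                                    noise_sigma_f14c = 0.01, seed = 4), crv)
  expect_equal(unique(co$donors$sigma[1:5]), 0.01)
  expect_equal(unique(co$donors$sigma[6:10]), 0.02)
  expect_equal(unique(co$donors$batch_id), c("B01", "B02"))
})

test_that("raw records invert the whole reduction chain to machine precision", {
  crv <- fixture_curve()
  spec <- cohort_spec(noise_sigma_f14c = 0, seed = 17)
  raw <- generate_raw_records(spec, crv)
  red <- fraction_modern(raw$records)
  red <- background_correct(red, f14c_value(raw$records$machine_background, 0))
  # reduction recovers the mixed (sample + blank) values
  expect_equal(red$f14c, raw$truth$f14c_measured, tolerance = 1e-9)
  # per-donor blank correction then recovers the true values
  rec <- mapply(function(i) {
    blank_mass_correct(f14c_value(red$f14c[i], red$sigma[i]), raw$blanks[[i]],
                       raw$records$carbon_mass_total[i])$f14c
  }, seq_len(nrow(raw$records)))
  expect_equal(unname(rec), raw$truth$f14c_true, tolerance = 1e-9)
  # draws respect the stated mass windows
  expect_true(all(raw$truth$mass_blank >= 10 & raw$truth$mass_blank <= 20))
  expect_true(all(raw$records$carbon_mass_total >= 70 &
                  raw$records$carbon_mass_total <= 120))
})

test_that("emitted ratios carry the delta-13C fractionation factor", {
  # identical targets at different delta13c differ by the squared factor
  f_meas <- 1.25
  frac <- function(d) (0.975 / (1 + d / 1000))^2
  r1 <- f_meas * 0.95 / frac(-21.2)
  r2 <- f_meas * 0.95 / frac(-25)
  expect_equal(r1 / r2, frac(-25) / frac(-21.2), tolerance = 1e-12)
  v1 <- fraction_modern(ams_record("a", r1, 1, -21.2, 100))$f14c
  v2 <- fraction_modern(ams_record("b", r2, 1, -25, 100))$f14c
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, f_meas, tolerance = 1e-12)
})

test_that("a noiseless raw cohort closes the loop to the identity regression", {
  crv <- fixture_curve()
  spec <- cohort_spec(n_donors = 10, birth_year_range = c(1956, 1964),
                      collection_year = 2000, noise_sigma_f14c = 0, seed = 23)
  raw <- generate_raw_records(spec, crv)
  donors <- as.data.frame(raw$records)
  donors$donor_id <- donors$sample_id
  # reduce with the matching per-donor blank, then calibrate on the limb
  red <- fraction_modern(raw$records)
  red <- background_correct(red, f14c_value(raw$records$machine_background, 0))
  donors$f14c <- vapply(seq_len(nrow(donors)), function(i)
    blank_mass_correct(f14c_value(red$f14c[i], red$sigma[i]), raw$blanks[[i]],
                       donors$carbon_mass_total[i])$f14c, numeric(1))
  donors$sigma <- 1e-6
  donors <- donors[, c("donor_id", "birth_year", "collection_year",
                       "f14c", "sigma")]
  p <- predict_birth_years(donors, crv,
                           pipeline_config(prior_range = c(1955, 1965),
                                           grid_step = 0.01))
  r <- regress_cohort(p)
  expect_equal(r$slope, 1, tolerance = 5e-3)
  expect_lt(abs(r$intercept), 10)
  expect_gt(r$r_squared, 0.999)
})

test_that("cohort files are written with their truth sidecar", {
  crv <- fixture_curve()
  co <- generate_cohort(cohort_spec(n_donors = 5, seed = 12), crv)
  prefix <- tempfile()
  write_cohort(co, prefix)
  expect_true(file.exists(paste0(prefix, "_donors.csv")))
  expect_true(file.exists(paste0(prefix, "_truth.csv")))
  back <- read_donors(paste0(prefix, "_donors.csv"))
  expect_equal(nrow(back), 5)
})
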