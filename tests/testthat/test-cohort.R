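test_that("the validation regression reproduces hand-computed OLS", {
  d <- data.frame(birth_year = c(1960, 1970, 1980, 1990),
                  predicted_year = c(1961, 1969, 1980, 1990))
  r <- regress_cohort(d)
  # cov 490 / var 500, intercept 1975 (1 - 0.98), SS_res 1.8 / SS_tot 482
  expect_equal(r$slope, 0.98, tolerance = 1e-10)
  expect_equal(r$intercept, 39.5, tolerance = 1e-8)
  expect_equal(r$r_squared, 1 - 1.8 / 482, tolerance = 1e-10)
  expect_equal(round(r$r_squared, 4), 0.9963)
  expect_equal(r$n, 4)
  expect_gt(r$slope_se, 0)

  # perfectly collinear points sit on the identity line
  dc <- data.frame(birth_year = c(1950, 1960, 1980),
                   predicted_year = c(1950, 1960, 1980))
  rc <- suppressWarnings(regress_cohort(dc))  # lm warns on a perfect fit
  expect_equal(rc$slope, 1)
  expect_equal(rc$intercept, 0, tolerance = 1e-9)
  expect_equal(rc$r_squared, 1)

  expect_error(regress_cohort(d[1:2, ]), "at least 3")
  expect_error(regress_cohort(data.frame(birth_year = rep(1960, 4),
                                         predicted_year = 1:4 + 1960)),
               "degenerate")
})

test_that("a noise-free cohort on one limb regresses to the identity line", {
  crv <- fixture_curve(0.05, sigma = 1e-4)
  births <- seq(1956, 1964, length.out = 12)
  d <- data.frame(donor_id = sprintf("D%02d", 1:12), birth_year = births,
                  collection_year = 2000,
                  f14c = curve_at(crv, births)$f14c, sigma = 1e-6)
  p <- predict_birth_years(d, crv,
                           pipeline_config(prior_range = c(1955, 1965),
                                           grid_step = 0.01))
  r <- regress_cohort(p)
  expect_equal(r$slope, 1, tolerance = 1e-3)
  expect_lt(abs(r$intercept), 2)
  expect_gte(r$r_squared, 0.9999)
})

test_that("raw AMS donors are reduced, calibrated, and errors stay isolated", {
  crv <- fixture_curve()
  good <- data.frame(
    donor_id = c("A", "B"), sample_id = c("A", "B"),
    ratio_sample = 0.95 * c(1.30, 1.45), ratio_standard = 1.0,
    delta13c = -25, carbon_mass_total = 100, batch_id = "B1",
    machine_background = 0,
    birth_year = c(1975, 1958.5), collection_year = 2000)
  cfg <- pipeline_config(prior_range = c(1955, 2000))
  p1 <- predict_birth_years(good, crv, cfg)
  expect_true(all(is.finite(p1$predicted_year)))

  # inject a donor whose blank mass exceeds its carbon mass
  bad <- good[1, ]
  bad$donor_id <- bad$sample_id <- "C"
  bad$carbon_mass_total <- 10
  cfg2 <- pipeline_config(prior_range = c(1955, 2000),
                          blank = blank_model(0.6, 0.01, 15, 2))
  p2 <- predict_birth_years(rbind(good, bad), crv, cfg2)
  expect_true(is.na(p2$predicted_year[3]))
  expect_match(p2$flags[3], "correction error")
  # the failing donor does not perturb the others
  p2ref <- predict_birth_years(good, crv, cfg2)
  expect_equal(p2$predicted_year[1:2], p2ref$predicted_year)
  expect_equal(p2$predicted_sigma[1:2], p2ref$predicted_sigma)
})

test_that("a noiseless donor round-trips through the pipeline to its birth year", {
  crv <- fixture_curve()
  b <- 1972.3
  d <- data.frame(donor_id = "X", birth_year = b, collection_year = 2000,
                  f14c = curve_at(crv, b)$f14c, sigma = 1e-6)
  p <- predict_birth_years(d, crv, pipeline_config(prior_range = c(1966, 2000)))
  expect_equal(p$predicted_year, b, tolerance = 0.05)
  # the nearest-reference rule picks the rising limb when asked
  d2 <- data.frame(donor_id = "Y", birth_year = 1960.5, collection_year = 2000,
                   f14c = 1.300, sigma = 0.005)
  p2 <- predict_birth_years(d2, crv, pipeline_config(point_rule = "nearest"))
  expect_equal(p2$predicted_year, 1960.25, tolerance = 0.05)
  expect_match(p2$point_rule, "nearest")
})

test_that("donor files round-trip and pipeline output is byte-deterministic", {
  crv <- fixture_curve()
  co <- generate_cohort(cohort_spec(n_donors = 6, seed = 99), crv)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_donors(co$donors, f1)
  back <- read_donors(f1)
  expect_equal(back$donor_id, co$donors$donor_id)
  expect_equal(back$f14c, co$donors$f14c, tolerance = 1e-12)

  p <- predict_birth_years(co$donors, crv, pipeline_config())
  write_donors(p, f1)
  write_donors(predict_birth_years(co$donors, crv, pipeline_config()), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(read_donors(write_curve_file(
    c("a,1,2", "b,2,3"), header = "donor_id,x,y")), "missing column")
})

test_that("weighted regression downweights poorly dated donors", {
  d <- data.frame(birth_year = c(1960, 1970, 1980, 1990),
                  predicted_year = c(1960.2, 1969.8, 1980.1, 1999),
                  predicted_sigma = c(0.3, 0.3, 0.3, 30))
  rw <- regress_cohort(d, weighted = TRUE)
  ru <- regress_cohort(d)
  expect_lt(abs(rw$slope - 1), abs(ru$slope - 1))
})
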