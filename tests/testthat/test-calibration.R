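test_that("the calibration likelihood peaks at the truth and flags no-support", {
  crv <- fixture_curve()
  grid <- seq(1966, 1995, by = 0.05)
  truth <- 1975
  meas <- f14c_value(curve_at(crv, truth)$f14c, 0.01)
  lik <- likelihood_over_years(meas, crv, grid)
  expect_true(all(is.finite(lik)) && all(lik >= 0))
  expect_equal(grid[which.max(lik)], truth)

  far <- likelihood_over_years(f14c_value(3.0, 0.01), crv, grid)
  expect_true(all(far < 1e-20))
  expect_true(isTRUE(attr(far, "no_support")))
})

test_that("a post-bomb value yields two modes matching the brute-force oracle", {
  crv <- fixture_curve()
  cal <- calibrate(f14c_value(1.300, 0.005), crv, grid_step = 0.05)
  expect_equal(nrow(cal$modes), 2)
  # within-mode means sit at the two limb crossings
  expect_equal(cal$modes$mean[1], (1.300 - 0.969) / 0.0631 + 1955,
               tolerance = 0.05)
  expect_equal(cal$modes$mean[2], 1965 + 16 * log(2), tolerance = 0.05)
  # falling-limb mode carries the larger mass, ratio ~ |slopes| 0.0631/0.01875
  ratio <- cal$modes$mass[2] / cal$modes$mass[1]
  expect_gt(ratio, 3.0)
  expect_lt(ratio, 3.8)
  expect_equal(cal$selected_mode, 2)

  # independent brute-force posterior: same mode masses and means
  bp <- brute_posterior(1.300, 0.005, crv, 1900, 2000)
  above <- bp$post > max(bp$post) * 1e-3
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  expect_equal(length(keep), 2)
  for (m in 1:2) {
    j <- starts[keep[m]]:ends[keep[m]]
    expect_equal(cal$modes$mass[m], sum(bp$post[j]), tolerance = 2e-3)
    expect_equal(cal$modes$mean[m],
                 sum(bp$grid[j] * bp$post[j]) / sum(bp$post[j]),
                 tolerance = 0.02)
  }
})

test_that("a pre-bomb value gives a single broad mode containing 1950", {
  crv <- fixture_curve()
  cal <- calibrate(f14c_value(0.9700, 0.0005), crv)
  expect_equal(nrow(cal$modes), 1)
  expect_true(cal$modes$year_lo[1] <= 1950 && 1950 <= cal$modes$year_hi[1])
  # the flat Suess limb is nearly uninformative at curve sigma 0.005, so the
  # point estimate is checked against the independent brute-force mean
  bp <- brute_posterior(0.9700, 0.0005, crv, 1900, 2000)
  expect_equal(cal$point_estimate, sum(bp$grid * bp$post), tolerance = 0.1)
})

test_that("posterior mass is exactly normalized and stable under grid halving", {
  crv <- fixture_curve()
  cases <- list(c(1.300, 0.005), c(1.120, 0.010), c(1.550, 0.002),
                c(0.975, 0.003), c(1.067, 0.008))
  for (cs in cases) {
    cal <- calibrate(f14c_value(cs[1], cs[2]), crv, grid_step = 0.05)
    expect_lt(abs(sum(cal$posterior) - 1), 1e-9)
    half <- calibrate(f14c_value(cs[1], cs[2]), crv, grid_step = 0.025)
    if (nrow(cal$modes) == nrow(half$modes))
      expect_true(all(abs(cal$modes$mass - half$modes$mass) < 1e-3))
  }
})

test_that("values between the post-bomb minimum and the peak are bimodal", {
  crv <- fixture_curve()
  set.seed(7)
  for (v in runif(15, 1.08, 1.58)) {
    cal <- calibrate(f14c_value(v, 1e-3), crv)
    expect_equal(nrow(cal$modes), 2)
    # HPD intervals lie inside the prior and 68 within 95 total mass
    expect_true(all(cal$hpd_68$year_lo >= 1900 & cal$hpd_68$year_hi <= 2000))
    expect_lte(sum(cal$hpd_68$mass), sum(cal$hpd_95$mass) + 1e-9)
  }
})

test_that("monotone inversion matches the closed-form limb solutions", {
  crv <- fixture_curve(0.01)
  expect_equal(invert_monotone(1.300, crv, c(1965, 2000)), 1965 + 16 * log(2),
               tolerance = 1e-4)
  expect_equal(invert_monotone(1.300, crv, c(1955, 1965)),
               (1.300 - 0.969) / 0.0631 + 1955, tolerance = 1e-5)
  # a knot value inverts to its own year
  expect_equal(invert_monotone(curve_at(crv, 1975)$f14c, crv, c(1965, 2000)),
               1975, tolerance = 1e-5)
  expect_error(invert_monotone(1.300, crv, c(1950, 1980)), "monotone")
  expect_error(invert_monotone(2.0, crv, c(1965, 2000)), "domain error")
})

test_that("with vanishing measurement sigma the point estimate meets the oracle", {
  crv <- fixture_curve()
  cal <- calibrate(f14c_value(1.300, 1e-6), crv, prior_range = c(1966, 2000),
                   grid_step = 0.05)
  root <- invert_monotone(1.300, crv, c(1966, 2000))
  expect_lt(abs(cal$point_estimate - root), 2 * 0.05)
  expect_equal(root, 1976.091, tolerance = 1e-3)
})

test_that("the nearest-reference point rule selects the requested limb", {
  crv <- fixture_curve()
  cal <- calibrate(f14c_value(1.300, 0.005), crv, point_rule = "nearest",
                   reference_year = 1960.5)
  expect_equal(cal$point_estimate, 1960.25, tolerance = 0.05)
  expect_match(cal$point_rule, "nearest")
})

test_that("degenerate priors and likelihoods are rejected", {
  crv <- fixture_curve()
  expect_error(calibrate(f14c_value(1.3, 0.005), crv,
                         prior_range = c(1890, 2000)), "prior")
  zc <- atm_curve(c(1960, 1970), c(1.2, 1.4), c(0, 0))
  expect_error(calibrate(f14c_value(1.25, 0), zc, grid_step = 5),
               "degenerate")
})
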