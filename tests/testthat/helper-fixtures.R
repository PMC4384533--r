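# Shared fixtures built in code at test time.

fixture_curve <- function(grid_step = 0.05, sigma = 0.005)
  synthetic_bomb_curve(grid_step, sigma = sigma)

# Affine atmospheric history F(u) = 1 + slope (u - ref); linear in u, so
# interpolation is exact and the turnover integral has a closed form.
affine_curve <- function(slope = 0.01, ref = 1950, from = 1940, to = 2000,
                         sigma = 0.005) {
  yr <- seq(from, to, by = 0.5)
  atm_curve(yr, 1 + slope * (yr - ref), rep(sigma, length(yr)))
}

# Closed form of the one-compartment response to an affine atmosphere:
# F(T) = a + b T - (b/k) (1 - exp(-k (T - t0))) with F_atm(u) = a + b u.
affine_turnover_closed_form <- function(k, t0, Tn, slope = 0.01, ref = 1950) {
  (1 + slope * (Tn - ref)) - (slope / k) * (1 - exp(-k * (Tn - t0)))
}

write_curve_file <- function(rows, path = tempfile(fileext = ".csv"),
                             header = "year,f14c,sigma") {
  writeLines(c(header, rows), path)
  path
}

# Independent brute-force posterior on a fine grid (the calibration oracle):
# straight dnorm over the interpolated curve, normalized by its sum.
brute_posterior <- function(f, sig, curve, lo, hi, by = 0.01) {
  grid <- seq(lo, hi, by = by)
  cv <- curve_at(curve, grid)
  dens <- dnorm(f, cv$f14c, sqrt(sig^2 + cv$sigma^2))
  list(grid = grid, post = dens / sum(dens))
}
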