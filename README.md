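# lenscarbon

Bomb-pulse radiocarbon dating of post-mitotic tissue carbon, built around
the human ocular lens lipid application.

Above-ground nuclear testing (1955–1963) nearly doubled atmospheric
¹⁴CO₂; the excess has since decayed quasi-exponentially. Carbon fixed from
the atmosphere therefore carries a date stamp: the fraction modern
(F14C) of a biomolecule can be inverted against the atmospheric record to
date its biosynthesis. In the lens nucleus — formed *in utero* and never
replaced — this turns an AMS measurement on extracted membrane lipids into
a predicted year of birth, and a cohort of donors with documented birth
dates into a direct test of whether lens lipids turn over at all.

The package implements the full inference chain for researchers running or
re-analysing such studies:

* **AMS reduction** — raw ¹⁴C/¹²C ratios with δ¹³C fractionation
  normalization (`fraction_modern`), machine-background subtraction
  (`background_correct`), and procedural-blank mass balance with
  first-order error propagation (`blank_mass_correct`):
  `f_sample = (f_meas·M − f_blank·m_b)/(M − m_b)`.
* **Calibration** — CALIbomb-style inversion of F14C ± σ to a posterior
  over calendar years (`calibrate`), with likelihood variance
  `σ²_meas + σ²_curve(t)`, explicit multimode handling (the rising and
  falling limbs of the pulse), HPD intervals, and two point rules;
  `invert_monotone` is the deterministic single-limb oracle.
* **Turnover** — a one-compartment exchange model
  `F(T) = e^{−kΔ}F_atm(t0) + ∫ k e^{−k(T−u)} F_atm(u) du`
  (`predict_f14c`) and a profile-likelihood fit of the rate with
  boundary-corrected test against k = 0 (`fit_turnover`).
* **Contamination** — stable-isotope mass balance for ¹³C-labelled-solvent
  retention checks (`infer_contamination_fraction`,
  `mix_delta`, `atom_fraction_to_delta`).
* **Cohort pipeline** — per-donor reduce → calibrate → point estimate
  (`predict_birth_years`) and the predicted-versus-actual birth-year OLS
  validation regression (`regress_cohort`).
* **Synthetic data** — seeded generators (`generate_cohort`,
  `generate_raw_records`) emulating a 23-donor study with realistic blanks,
  target masses and per-batch precision, plus a synthetic
  southern-hemisphere-shaped bomb-pulse fixture curve
  (`synthetic_bomb_curve`); real hemispheric compilations can be supplied
  as `year,f14c,sigma` tables via `read_curve` and `splice_curves`.

A thin CLI (`exec/lenscarbon`) exposes `calibrate`, `cohort`,
`turnover-fit`, `contamination` and `simulate` subcommands over the same
functions.

## Worked example

```r
library(lenscarbon)
curve <- synthetic_bomb_curve(0.05)

# A post-bomb measurement is bimodal: one solution per limb of the pulse
calibrate(f14c_value(1.300, 0.005), curve)
#> F14C calibration of 1.3000 +/- 0.0050 on prior [1900.00, 2000.00]
#>   2 mode(s):
#>     [1959.85, 1960.65] mass 0.229 mean 1960.25
#>    *[1974.75, 1977.55] mass 0.771 mean 1976.10
#>   point estimate 1976.10 +/- 0.38 (highest-mass)
```

The falling limb carries ~3.4× the mass of the rising limb because it is
that much flatter; the point estimate is the posterior mean within the
highest-mass mode and its uncertainty the half-width of that mode's 68.3%
HPD interval.

```r
# Simulate a 23-donor validation cohort and run the whole pipeline
cohort <- generate_cohort(
  cohort_spec(n_donors = 23, birth_year_range = c(1966, 1993),
              collection_year = 2000, noise_sigma_f14c = 0.01, seed = 1),
  curve)
pred <- predict_birth_years(cohort$donors, curve, pipeline_config())
regress_cohort(pred)
#> Predicted vs actual birth year (OLS, n = 23)
#>   slope     0.9796 +/- 0.0161
#>   intercept 40.2 +/- 32.0 yr
#>   R^2       0.9943

fit_turnover(cohort$donors, curve)
#> Turnover fit (n = 23 donors)
#>   k_hat = 0 /yr, 68% CI [0, 0.0003283], 95% CI [0, 0.000748]
#>   LRT vs k = 0: 0.000 (one-sided boundary-corrected p = 1)
#>   no-turnover hypothesis (k = 0) is inside the 95% CI
```

A slope near one, an intercept near zero and R² near one say the predicted
birth dates track the documented ones; the rate fit bounds any turnover at
well under 0.1%/yr for this (no-turnover) cohort.

```r
# Solvent-retention check: a 1.5 permil shift under a +900 permil tracer
infer_contamination_fraction(delta_value(-21.2, 0.7),
                             delta_value(-22.7, 0.1), delta_value(900))
#>   contaminant carbon fraction 0.001626 +/- 0.00077 (0.1626%)
```

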