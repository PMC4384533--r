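---
title: "Bomb-pulse dating of lens lipids: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bomb-pulse dating of lens lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenscarbon)
```

## The scientific problem

Above-ground nuclear weapons testing (1955–1963) nearly doubled the
atmospheric ¹⁴CO₂ inventory; since the test-ban treaty the excess has
decayed quasi-exponentially into the oceans and biosphere. Any biomolecule
whose carbon was fixed from the atmosphere therefore carries a date stamp:
its fraction modern (F14C) can be matched against the atmospheric record to
recover the year of biosynthesis. In post-mitotic tissue such as the ocular
lens nucleus — whose fiber cells form *in utero* and are never replaced —
this turns a radiocarbon measurement on extracted membrane lipids into a
predicted year of birth. If, on the other hand, the lipid pool exchanged
carbon with the body's metabolic pool, the measured F14C would be pulled
toward the atmosphere of the collection date. The package implements the
full inference chain:

1. **AMS reduction** — raw isotope ratios → blank-corrected F14C ± σ;
2. **calibration** — F14C → posterior over calendar years (CALIbomb-style);
3. **turnover** — a one-compartment exchange model adjudicating
   "no turnover" against a finite exchange rate;
4. **contamination** — a stable-isotope mass balance for the
   ¹³C-labelled-solvent retention check;
5. **cohort pipeline** — per-donor predictions and the predicted-versus-
   actual birth-year validation regression;
6. **synthetic data** — a generator reproducing the statistical structure
   of a 23-donor study, so every stage is testable without any download.

## Data reduction

Fraction modern is defined against 95% of the fractionation-normalized
oxalic-acid-I activity; the sample ratio is normalized to δ¹³C = −25‰ with
the squared factor

$$ f = \frac{R_\text{sample}\,[0.975/(1+\delta^{13}\mathrm{C}/1000)]^2}
          {0.95\, R_\text{OxI}^{(-19)}}. $$

The standard ratio is taken as already normalized to −19‰, the
international convention. Two corrections follow. The **machine
background** (radiocarbon-free graphite) is subtracted linearly — adequate
because backgrounds are orders of magnitude below the signal — with sigmas
combined in quadrature, and values clipped at zero with a flag. The
**procedural blank** is removed by a two-component mass balance with
total-mass semantics: the combusted target of mass $M$ is sample plus blank
carbon, so

$$ f_\text{sample} = \frac{f_\text{meas} M - f_\text{blank} m_b}{M - m_b}, $$

with the one-sigma propagated to first order over
$(f_\text{meas}, f_\text{blank}, m_b)$; $M$ is measured manometrically and
treated as exact. This form is fixed by construction and tested as the
exact inverse of forward mixing (to 1e-12) rather than inferred from any
external parameterization. Measurement sigmas follow a per-batch precision
policy — 0.5% relative at/above 50 μg of carbon, 2% below, with optional
per-batch multipliers — reflecting how precision varies with target size
and handling line. F14C is treated as already decay-standardized; no
additional decay correction is applied over decadal spans (the calibration
curve uses the same convention, and the effect is below 1%).

## Calibration

The likelihood of calendar year $t$ for a measurement $f \pm \sigma$ is
Gaussian with mean $F_\text{atm}(t)$ and variance
$\sigma^2 + \sigma_\text{curve}(t)^2$; the posterior is this likelihood
normalized over a uniform prior grid (default: the full curve domain at
0.05 yr). Curve value and curve sigma are interpolated linearly — the
reproducible, oracle-checkable choice. No extrapolation is allowed.

Because the pulse rises and falls, a post-bomb value generically has two
solutions. Modes are maximal contiguous grid runs with posterior above
peak × 1e-3; each reports its interval, mass, and within-mode mean. HPD
intervals (68.3% / 95.4%) use descending-density inclusion. Two point
rules are provided: the default takes the posterior mean within the
highest-mass mode (ties toward the earlier mode); the alternative
`"nearest"` rule picks the mode closest to a documented reference year, the
natural choice in validation studies where the birth date is known. The
rule used is recorded per donor.

Numerical notes, all of which the test-suite pins down:

* posterior mass sums to 1 within 1e-9 by construction;
* on a monotone limb the posterior mean converges to the deterministic
  bisection inverse (`invert_monotone`, 1e-6 yr) as the measurement sigma
  shrinks — but only as the *total* variance shrinks: the curve sigma puts
  a floor under the posterior width, and on a convex limb this shifts the
  mean by approximately $3\sigma^2 F''/(2 F'^3)$, a fraction of a year near
  the end of the falling limb;
* two modes merge into one when the inter-mode density dip exceeds the
  splitting threshold, which happens for values within roughly 0.02 F-units
  of the 1.600 fixture peak at the fixture's sigma of 0.005 — so bimodality
  holds on the interior of the (minimum, peak) value range, not arbitrarily
  close to the peak;
* the flat pre-bomb limb (Suess decline, −0.0002/yr) is nearly
  uninformative at realistic uncertainties: a pre-bomb value dates to a
  decades-wide single mode. This is faithful to the physics; documented
  rather than hidden.

## The turnover model

The pool obeys $\mathrm{d}F/\mathrm{d}t = k\,(F_\text{atm}(t) - F)$ from
birth $t_0$ to collection $T$:

$$ F(T) = e^{-k\Delta} F_\text{atm}(t_0)
        + \int_{t_0}^{T} k\, e^{-k(T-u)} F_\text{atm}(u)\, \mathrm{d}u,
        \qquad \Delta = T - t_0, $$

an exponentially weighted average of the atmospheric history with weight
$e^{-k\Delta}$ on the birth value. The limits are honoured exactly:
$k = 0$ returns the birth-year atmosphere (no integral is evaluated, so
only the birth year needs to lie in the curve domain) and $k \to \infty$
the collection-year atmosphere. The integral uses composite trapezoidal
quadrature at 0.05 yr, with the step shrunk as $1.5\times10^{-3}/k$ for
fast rates because the trapezoid error grows as $(hk)^2$; this keeps
agreement with the affine-curve closed form below 1e-6 across the rate
range, which the tests verify at the default step.

`fit_turnover` profiles the Gaussian measurement log-likelihood over a
fixed rate grid (0 plus 60 log-spaced points in $[10^{-4}, 1]$ /yr), with
measurement sigmas taken as known from the reduction. The grid keeps the
scan deterministic, but with an informative cohort the profile is far
sharper than the grid, so confidence bounds are *root-found* on the
continuous profile at the likelihood-ratio thresholds (deviance 1.00 and
3.84) between the bracketing grid points, and the argmax is polished by
golden-section search — both deterministic. The test against no turnover
is the likelihood ratio at $k = 0$; since the null sits on the boundary,
the p-value uses the 50:50 mixture of a point mass and χ²(1). Measured
95% CI coverage in the test suite's simulations (n = 23, 200 replicates)
is 0.98 at $k = 0$ (conservative, as expected at a boundary) and about
0.95 at $k = 0.10$/yr.

## Contamination mass balance

A ¹³C-enriched solvent acts as a tracer for solvent retention. With linear
(weight-fraction) delta mixing — within 0.1‰ of exact ratio mixing at
these enrichments — the retained carbon fraction is

$$ f = \frac{\delta_\text{obs} - \delta_\text{base}}
            {\delta_\text{source} - \delta_\text{base}}, $$

with first-order error propagation and negative solutions clipped to zero
with a flag. The conversion between atom fraction and delta uses
$R_\text{VPDB} = 0.0111802$. A worked case in the tests: a shift from
−22.7‰ to −21.2‰ under a +900‰ source gives $f = 1.5/922.7 \approx
1.63\times10^{-3}$; the same shift under a 10-atom-% source (+8938‰) gives
$1.67\times10^{-4}$. The package deliberately reports $f$ for whatever
source delta the user specifies and asserts no particular published
percentage: the mapping from "10% enriched methanol" to a mixture-level
source delta is ambiguous (methanol-level vs solvent-level enrichment),
and the two readings differ by an order of magnitude.

## The synthetic generator and what it does (not) emulate

`cohort_spec()` defaults encode the study conditions: 23 donors, birth
dates mid-year from 1948.5 to 1993.5 (a documented year of birth is taken
as YYYY.5, matching a ±six-months convention), collection in 2010,
no turnover, noise sd 0.01 in F14C, blanks of 10–20 μg against 70–120 μg
targets, batches of 5 with optional per-batch precision multipliers. One
seeded generator drives all draws; the seed is recorded in the truth
sidecar, which is kept separate from the donor table so blinded tests are
possible. `generate_raw_records()` inverts the entire reduction chain
(mix blank, add background, emit ratios at δ¹³C drawn near −22.7‰), so
reducing its output recovers the generated values to 1e-9 — the
full-pipeline closure test.

The supplied calibration curve is a synthetic southern-hemisphere-shaped
fixture: a Suess-style decline 0.980 − 0.0002 (t − 1900) to 1955, a linear
rise to a 1.600 peak at 1965, then exponential decay with a 16-yr
e-folding time, sigma 0.005 throughout, tabulated on [1900, 2000]. It
mimics the shape of the real hemispheric compilations but is not measured
data; users with access to a published compilation can supply it as a
`year,f14c,sigma` table and splice a tree-ring pre-bomb record onto it
with `splice_curves()`. Passing tests on the fixture therefore demonstrate
the *inference machinery* — inversion, multimodality handling, error
propagation, rate recovery — not agreement with any measured atmospheric
record. Two known idealizations: no food-chain lag between atmosphere and
tissue carbon (lipid carbon is taken to reflect the birth-year
atmosphere directly), and a single well-mixed lipid pool rather than
class-specific turnover.

## Problem sizes and reproducibility choices

The validation simulation mirrors a 23-donor cohort on the falling limb
(births 1966–1993), where calibration is single-limbed for most draws and
the regression is a clean end-to-end summary; 1% measurement noise there
maps to between a quarter year (1966) and one and a half years (1993) of
date uncertainty, because the limb flattens as the pulse decays. The
no-noise variant of that regression is run with the fixture shape at curve
sigma 1e-4 and measurement sigma 1e-6 on a 0.01-yr grid: the identity line
(slope 1, intercept 0, R² = 1) is recovered only in the limit of vanishing
*total* variance, since the curvature shift described above otherwise
biases the slope by a few parts per thousand. Rate-recovery simulations
use 200 replicates per scenario. These sizes were chosen to make every
stochastic claim measurable with comfortable margin while keeping the
whole suite near half a minute.

## Known limitations

* The pre-bomb limb is nearly flat; birth dates before 1955 are
  essentially unconstrained by a single F14C measurement at realistic
  precision. Real studies resolve this with the documented collection date
  and the monotone post-bomb context; the `"nearest"` point rule plays
  that role here.
* Posterior means near the domain edge (roots within a few posterior sd of
  the curve end) are biased inward by truncation; the calibration refuses
  to extrapolate rather than guessing.
* The turnover fit assumes known, Gaussian, independent measurement
  errors; it does not re-estimate a dispersion parameter.
* Weighted regression (1/σ² on the predicted year) is available behind a
  flag but is not the default, since the headline validation line is an
  unweighted OLS.
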