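---
title: "Assessing trace-metal accumulation and health risk from organic fertilizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trace-metal accumulation and health risk from organic fertilizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertrisk)
```

`fertrisk` models what repeated application of composted organic
fertilizer does to farmland soil and, through soil contact, to people.
This vignette is the package's account of the science: the models and
their assumptions, the parameters that matter, the design decisions that
were genuinely open, and what the tests do and do not establish.

## The assessment chain

Seven trace metals are tracked — Cr, Ni, Cu, Zn, As, Cd, Pb, in that
fixed order everywhere (As is a metalloid but is treated identically).
Three surveyed regions of northern China (north, northwest, northeast,
with 48/55/14 samples) each carry their own soil backgrounds `Q0`
(mg/kg), bulk density `rho_b` (g/cm³) and fertilizer application rate
`IR_f` (t·hm⁻²·yr⁻¹), shipped as CSV and loaded with
`load_region_parameters()`.

### Soil accumulation

One application year adds, per kg of plow-layer soil,

$$Q_{p,i} = \frac{IR_f \, \alpha_i}{\rho_b \, V},$$

where $\alpha_i$ is the fertilizer concentration of metal $i$ (mg/kg
dry weight) and $V = 2000$ m³/hm² is the volume of the 20 cm plow
layer; the tonne-to-kg conversions of fertilizer mass and soil mass
cancel. Accumulation is linear and lossless, $Q_i(n) = Q_{0,i} + n
Q_{p,i}$, so the years to the GB15618-2018 dry-land soil limit
$C_{s,i}$ (pH > 7.5 class: 250/190/100/300/25/0.6/170 mg/kg) have the
closed form $T_i = (C_{s,i} - Q_{0,i})/Q_{p,i}$, with $T = \infty$ for
zero flux and $T = 0$ (flagged) when the background already exceeds
the limit. The identity $Q_0 + T\,Q_p = C_s$ holds to machine
precision and is tested as such.

Ignoring losses (leaching, runoff, crop uptake) and gains (atmospheric
deposition) makes every $T$ conservative — slightly too short as an
estimate of when the limit is truly reached from fertilizer alone being
the only input, and the package deliberately keeps that bias rather
than inventing loss coefficients; the accumulation functions accept any
`Q0`/`Qp`, so a user with site-specific loss estimates can net them off
the flux.

### Exposure dosimetry

Three routes move soil metal into a farming adult: ingestion of soil
dust, dermal contact, and inhalation of suspended particles. All three
doses are linear in the exposed soil concentration $Q_i$:

* oral: $Q_{f,i} = Q_i\, IR_p\, EF_a\, ED_a\, c_i /(BW \cdot LT)\times 10^{-6}$
* dermal: $Q_{s,i} = Q_i\, EV\, SA\, \mu\, \eta\, EF_a\, ED_a\, c_i /(BW \cdot LT)\times 10^{-6}$
* inhalation: $Q_{b,i} = Q_i\, \omega\, IR_b\, ED_a\, c_i\,(f_{spod} EFOD_a + f_{spid} EFID_a)/(BW \cdot LT)\times 10^{-6}$

with the constants of `load_exposure_parameters()`: 100 mg/day
ingested, 250 exposure days/yr over 25 yr, 56.8 kg body weight, 26280
day lifetime, 1.614 m² skin (converted to cm² before the 0.2 mg/cm²
adherence factor; the 10⁻⁶ factor converts mg of soil to kg), 18% of
skin exposed, 0.15 mg/m³ suspended particulates breathed at 14.5
m³/day with outdoor/indoor soil-particle fractions 0.8/0.5 over
87.5/262.5 days/yr.

**The coefficient convention is the one genuinely awkward spot.** As
written, the three equations use route-specific absorption
coefficients: gastrointestinal $\beta_i$, skin $\gamma_i$, lung
$\theta_i$. But the reference result tables these computations are
validated against are only reproduced when $\beta_i$ is applied in all
three routes (e.g. the dermal Cd entry requires 5×10⁻², which is
$\beta_{Cd}$, not $\gamma_{Cd}=10^{-3}$). Both conventions are
implemented: `mode = "as_published"` (default, $\beta$ everywhere)
reproduces the reference tables; `mode = "as_written"` follows the
printed equations. The two differ by exactly $\gamma_i/\beta_i$
(dermal) and $\theta_i/\beta_i$ (inhalation), which the tests pin
down. Note that under `as_written` the dermal doses — and with them the
As/Cr cancer risks — drop by up to three orders of magnitude, so the
choice of convention is material and is always recorded in the risk
report.

The exposed concentration defaults to background plus **one**
application year of flux, `years = 1`, which is what reproduces the
reference hazard tables; the horizon is a plain argument.

### Risk indexing and grading

Hazard quotients divide each route dose by its route-specific reference
dose and sum over routes; the hazard index HI sums over all seven
metals, with 1.0 the concern threshold. Cancer risk multiplies the
summed doses of the four carcinogens (Cr, Ni, As, Cd) by their slope
factors; TCR sums them, with 10⁻⁶ negligible and 10⁻⁴ the maximum
acceptable. The qualitative grade crosses the HI bands (≤0.25 /
≤0.50 / ≤0.75 / ≤1.00, right-closed) with the TCR bands (≤10⁻⁶ /
≤10⁻⁵ / <10⁻⁴ / ≥10⁻⁴) in a 4×4 matrix; exactly 10⁻⁴ falls in the
explicit ≥10⁻⁴ band, and HI above 1.00 clamps to the extreme column
with a flag rather than erroring, since the matrix stops at 1.00.

Because every dose is linear in $Q_i$ and $Q_i$ is affine in the
application years, HI itself is affine in years, and
`years_to_hi_threshold()` solves the crossing in closed form. The
reference analysis reports materially shorter horizons (403 years for
the north, vs ~514 from this closed form with the same stated
parameters); the derivation behind those published figures is not
recoverable from the stated inputs, so the package stands behind the
closed form and certifies it against an independent year-by-year
stepping oracle in the tests rather than tuning toward the published
numbers.

### The pooled northern region

No aggregation rule is stated for the pooled "northern" results.
Reverse-engineering the reproducible pooled entries shows
sample-size-weighted means (48/55/14) of the regional backgrounds and
bulk densities combined with the *unweighted* arithmetic mean
application rate; `load_region_parameters("northern")` implements
exactly that and exposes the weights as an argument. Under this rule
the pooled Zn/Cd/As times (53/53/82 years) and the pooled HI (0.24) and
TCR (6.28×10⁻⁴ vs 6.29×10⁻⁴ published) reproduce; the slow metals
(Cr, Ni, Pb) land within ~1.5% of the published pooled row but not on
it, which is documented rather than patched.

## The synthetic survey generator

The original 117 samples were never deposited; what survives are
per-region summaries (range, mean, median, SD, CV, and a Shapiro–Wilk
p-value) showing strongly right-skewed concentrations (every mean above
its median, normality rejected almost everywhere). The generator
reproduces that structure with a lognormal per metal: log-location
$\ln(\text{median})$ and log-spread $\sigma = \sqrt{\ln(1 +
(CV/100)^2)}$, the closed-form CV relation for the lognormal. `cv = 0`
degenerates to a point mass, which is also how the Monte Carlo
simulation is collapsed onto the deterministic model in tests.

**Why draws are not truncated to the observed ranges by default.** The
published min/max are order statistics of 14–55 samples, not support
bounds. Hard truncation at them cuts exactly the upper tail that makes
these data heavy-tailed: simulated at n = 10⁴, the sample CV of every
high-CV metal lands 19–25% below its target under range truncation
(and for the most extreme spec — CV 171% inside a ×425 range — no
truncated lognormal matching the median can reach the target CV at
all). Untruncated, the generator recovers every regional median within
5% and every CV within 10% at n = 10⁴, which is the package's
parameter-recovery acceptance property. Truncation by rejection
sampling (never clipping, so no boundary atoms; capped at 10⁶ attempts
per draw) remains available via `truncate = TRUE` for genuinely bounded
scenarios, and an empirical-resampling family is provided when real
sample values exist.

Metals are generated independently by default; the co-sourcing
correlations seen in real manures (Cu–Zn, Cr–Pb, ...) are *not*
emulated unless a Spearman matrix is passed, in which case a Gaussian
copula (rank correlation converted by $2\sin(\pi\rho/6)$) induces the
dependence while preserving the marginals. Consequently, passing tests
on synthetic tables establishes the correctness of the statistical
machinery, not distributional claims about real fertilizer: in
particular, exceedance rates computed on synthetic surveys describe the
generator, and the published exceedance percentages (which require the
undeposited raw data) are validated only through tables constructed
with known exceedance counts.

## Monte Carlo time-to-limit

`mc_time_to_limit()` propagates the concentration distribution through
the accumulation model: each iteration draws one concentration per
metal, converts it to a flux and a time. Since $T$ is a monotone
(decreasing) function of the concentration, the simulated median
converges on the deterministic time at the distribution median — an
analytic oracle the tests exploit (agreement to <1% at 10⁵ draws, and
exact equality under a point mass). Quantiles use `type = 1` (inverse
empirical CDF): with infinite draws possible (a flux too small to ever
reach the limit), interpolating quantile types would manufacture NaN.
The simulation honours its seed exactly (identical seeds give identical
summaries) and scales the way the algebra says it must (doubling the
application rate halves every draw's time).

## Numerical and formatting choices

* **Rounding.** Published time rows round half away from zero;
  `round()` in R rounds half to even, so an explicit half-up rule is
  used for reported integer years. Times are always chained from the
  *unrounded* flux — rounding the flux first distorts slow metals by
  tens of years (928 becomes 945 for north-China Cr).
* **Exceedance is strict.** Limits are "maximum acceptable
  concentrations", so a sample exactly at the limit complies. The
  original convention is unknowable without the raw data; the choice is
  recorded here and in the screening report.
* **Spearman p-values** use the t-approximation for n > 10 and the
  exact null distribution for n ≤ 10 (falling back to the
  approximation under ties); correlations use midranks. Constant
  columns yield absent (NA) correlations, never fabricated ones.
* **Shapiro–Wilk** needs 3 ≤ n ≤ 5000 and positive spread; outside
  that the p-value is reported absent while the moments are still
  computed.
* **CV** uses the sample (n−1) standard deviation.

## Problem sizes

The shipped tests run the generator recovery at n = 10⁴ per region,
Monte Carlo checks at 10³–10⁵ iterations, and the survey property
checks at n = 48–500; the full suite completes in a few seconds. The
analysis scripts use 10⁵ Monte Carlo iterations per metal. These sizes
were chosen so that Monte Carlo error sits well inside the tolerances
being asserted (e.g. the simulated median time carries ~0.1 y of noise
at 10⁵ draws against a ±2 y check).

## Known limitations

* No loss or deposition terms in the soil model: times-to-limit are
  conservative by construction.
* Exposure is soil-contact only — no dietary/food-chain pathway, no
  child-specific parameters, no As speciation; absolute risks are
  therefore lower bounds on total exposure and the cancer-risk ranking
  across metals leans entirely on the slope factors used.
* The regions are single homogeneous distributions; manure-type
  composition within a region is not modelled.
* The standards registry is a frozen snapshot of the surveyed
  national limits and does not track regulatory updates.
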