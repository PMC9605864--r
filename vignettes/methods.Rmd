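---
title: "Methods: a modular Monte Carlo engine for the social cost of CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a modular Monte Carlo engine for the social cost of CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scco2)
```

The social cost of CO2 (SC-CO2) is estimated by a pulse experiment: run the
coupled socioeconomy–climate–damages model twice, identical except for a
small pulse of CO2 emissions in 2020, difference the monetized damages,
normalize per tonne, discount, and sum over 2020–2300. Repeating this over
jointly sampled scenario, climate, sea-level and damage-function
uncertainty gives a distribution of SC-CO2 values whose mean is the
risk-inclusive point estimate. This vignette documents the model equations,
the defaults and their units, the numerical choices, and what the synthetic
inputs do and do not represent.

## Scenario generator

One scenario draw supplies, for 2020–2300: country population, GDP per
capita and baseline all-cause mortality rates, and global CO2 (GtCO2/yr,
net, possibly negative), CH4 and N2O (Mt/yr) emissions.

World-level quantities are monotone transforms of standard normal shape
variables, anchored so the 5/50/95 quantiles of the printed summary
statistics are reproduced exactly in the transform (hence to Monte Carlo
error in any sample): 2300 world population (2.8/7.3/21 billion, lognormal
two-sided anchoring), cumulative-average per-capita growth 2020–2300
(0.17/0.88/2.7 %/yr, linear anchoring), and 2100 net CO2 emissions
(−7/17/62 GtCO2/yr, linear anchoring). Choices made where the design was
open:

* **Population path.** Log-population follows a two-sided Gaussian bump in
  time: rise from 7.8 billion (2020) to a peak (median 11 billion near
  2130, peak year jittered N(2130, 15²)), then decline to the anchored
  2300 level. The peak level shares the 2300 shape variable, so high draws
  rise monotonically through 2300 instead of peaking — consistent with the
  upper-quantile trajectories the anchors imply.
* **Income path.** Annual world log-growth declines linearly in time (tilt
  0.4, i.e. early growth about 1.4x the long-run average) while preserving
  the anchored cumulative average exactly. Country incomes are the world
  path times slowly converging country factors (log-gap decay 0.3 %/yr),
  renormalized each year so the population-weighted mean equals the world
  value exactly.
* **Emissions.** A cosine ramp from 42.5 GtCO2/yr (2020) to the anchored
  2100 level, then a 1 %/yr relative decline. The emissions shape variable
  is correlated with the growth shape variable through a Gaussian copula
  with coefficient 0.5 (configurable; 0 decouples them), which produces
  the positive growth–emissions rank correlation without disturbing the
  anchored marginal quantiles. Independence is assumed beyond this single
  link: the data behind the joint distribution do not pin down more
  copula structure, so we use the minimal one that carries it.
* **Population shares.** Country shares follow a slow multiplicative
  random walk (sd 0.002/yr) around a fixed size distribution, renormalized
  so country populations sum to the world total exactly. Country 1 is
  "USA" (4.3% of 2020 population, gdppc $63,000) because the mortality
  valuation needs a US income reference.
* **Mortality rates.** A deterministic schedule declining with income,
  `0.05 · gdppc^(−0.2)` clamped to [0.001, 0.04] — about 7.9 deaths per
  1,000 at gdppc $10,000. Demographic detail (age structure) is out of
  scope.

What the generator does *not* emulate: survey-weighted expert scenarios,
within-country demography, and any growth–population dependence. Passing
calibration tests therefore shows the marginal anchors and the one
specified coupling are right, not that the full joint distribution matches
real projections.

## Climate emulator

A reduced-complexity, emissions-driven emulator. Carbon is tracked in four
pools with partition fractions `a = (0.2173, 0.2240, 0.2824, 0.2763)` and
timescales `tau = (1e6, 394.4, 36.54, 4.304)` yr; each year the timescales
are scaled by a factor `alpha` solved so the 100-year integrated impulse
response equals `r0 + rU·U + rT·T` (`r0 = 35` yr, `rU = 0.019` yr/GtC,
`rT = 4.165` yr/K, `U` cumulative land+ocean uptake, `T` warming). The
response is strictly increasing in `alpha`, so bisection (in log `alpha`,
tolerance 1e-7 yr, warm-started from the previous year inside full runs)
finds the unique root; targets outside the attainable range at the bounds
[0.01, 100] are clamped (a warning from the standalone solver; counted per
run in `n_clamped` — this is the fully sink-saturated regime reached late
in high-emission draws). The discrete pool update
`R_i <- R_i e^{-1/(alpha tau_i)} + a_i E (alpha tau_i)(1 - e^{-1/(alpha tau_i)})`
conserves carbon to machine precision by construction (verified each step
to 1e-9 GtC). Concentration is `C0 + sum(R)/2.124` ppm.

Forcing: `F2x/ln 2 · ln(C/C0)` for CO2 (`F2x = 3.71` W/m²,
`C0 = 278` ppm), square-root forms for CH4/N2O (one-box lifetimes 9.3 and
121 yr), plus a packaged exogenous series for all other agents shaped like
a middle-of-the-road scenario. Temperature: two boxes with amplitudes
`q = (0.33, 0.41)` K/(W/m²) and timescales `d = (239, 4.1)` yr, implying
an equilibrium climate sensitivity of `F2x (q1+q2) ≈ 2.75` K at the
default parameters; the prior sampler spreads `q`, `F2x`, `r0`, `rU`,
`rT`. These defaults follow the widely used v1.6.2 configuration of this
emulator family; they are configuration, not constants, and a calibrated
ensemble CSV can replace the priors row-for-row.

The historical spin-up (1750–2019) uses packaged *synthetic* logistic
approximations to historical global emissions, shaped so the 2020 state is
internally consistent and lands near observed values (about 420 ppm and
1.0 K above 1850–1900); they are not observational series. Reported
anomalies are re-referenced to the 1850–1900 mean.

## Sea level

Five components, one state variable each, integrated annually along the
temperature path and re-referenced to 1900 (so the component-sum identity
is exact by construction):

* thermal expansion: relaxation `TE <- TE + (s·T − TE)/tau` with
  `s = 0.5` m/K, `tau = 200` yr;
* glaciers: `dV = beta0 (T − Teq)(V/V0)^n`, `beta0 = 5.8e-4` m/yr/K,
  `V0 = 0.41` m SLE, `Teq = −0.15` K, `n = 0.82`, volume bounded to
  [0, V0];
* Greenland: melt `max(0, 6e-4 · T)` m/yr, volume 7.4 m SLE;
* Antarctica: melt `4e-4 · T` plus a fast-disintegration rate
  `lambda = 0.01` m/yr whenever the Antarctic proxy temperature exceeds
  the threshold `Tcrit = 2.6` K. The proxy is 1.2x the global anomaly — a
  configurable stand-in, since the link between Antarctic surface and
  global temperature is not specified at this level of abstraction;
* land-water storage: constant 3e-4 m/yr.

Parameter uncertainty comes from documented independent priors (lognormal
on positive sensitivities, truncated normal on `Tcrit`) or from a
posterior-sample CSV drawn row-wise. Local sea level is the global total
times per-segment time-invariant scaling factors. The semi-empirical
single-state forms are deliberate simplifications of the multi-state
originals; upgrading any one component is localized to its step function.

## Damage sectors

**Energy** (12 regions): expenditure-share change `beta^E_j · T_t`, times
country GDP. `fit_energy_coefficients()` implements the through-origin
least-squares fit `beta = sum(x y)/sum(x^2)` used to derive the
coefficients from response tables.

**Mortality** (10 regions): excess deaths
`beta^M_j · T_t · population · baseline rate`, with `beta^M` drawn
per-region from `N(point estimate, SE²)`. Monetization uses
`VSL_{i,t} = $10.05M · (gdppc_{i,t}/gdppc_{US,2020})^ε` with ε = 1.
Excess deaths are *not* capped at baseline deaths; since the question is
open at this level of abstraction we leave the linear form uncapped and
report the number of country-years where excess exceeds baseline as a
diagnostic (`n_exceed_baseline`).

**Agriculture** (16 regions):
`AgPctCost = sigma_i (gdppc_{i,t}/gdppc_{i,1990})^{−0.31} f_theta(T_t)`,
times GDP. `theta ~ Triangular(0, 0.5, 1)` blends the low/central/high
piecewise-linear functions (anchors 0/0.5/1, nearest-pair linear
interpolation); each is linear from the origin to its 1 K knot and between
knots at 1, 2, 3 K. One global `theta` per draw preserves cross-region
covariance. Beyond 3 K the final segment is extended linearly
(configurable) because the functions are undefined there; negative
anomalies clamp to zero damages with a warning. Draws begin in 2020, so
the 1990 income base defaults to 0.65x the 2020 value (30 years at about
1.4 %/yr); tests that need the base-year identity pass it explicitly.
Sector coefficient defaults are synthetic-but-plausible placeholders at
the documented scale and are overridable by real supplementary tables.

**Coastal** (segment-level, deterministic given sea level): each planning
period (50 years, perfect foresight within the period — a chosen horizon,
reported in run metadata) the planner evaluates seven strategies per
segment: no adaptation (permanent inundation of the rising band plus
expected annual storm damage), retreat to the end-of-period sea level plus
the 10/100/1000-year surge return level (relocation at unit cost per
person plus abandoned capital, residual damage beyond the line), or
protect with a wall at that height plus a 0.5 m freeboard (construction
proportional to length and height increment, 2 %/yr maintenance, residual
overtopping damage). Surge heights follow segment GEV distributions;
expected storm damage integrates the GEV survival function numerically
(trapezoid on a 0–30 m grid, 5 cm step) times a uniform value density from
the linear elevation profile, with 25% of flooded value lost per
event-year. The least-cost strategy is chosen per period (ties toward no
adaptation, then retreat, then lower return periods); retreat lines and
walls persist. Costs here are documented simplifications — the decision
structure, not the cost calibration, is the point — and the 500 synthetic
segments are a seeded stand-in for a real coastal database, so absolute
coastal damages are small and should be read as structural, not
calibrated.

## Valuation

Consumption is world per-capita GDP net of total climate damages by
default (`consumption = "gross"` switches this off; the convention is
genuinely open, and net is chosen so damages feed back into the discount
path), floored at $100/person/yr so marginal utility stays finite; floored
draw-years are counted. The stochastic discount factor is
`SDF_t = (1+rho)^{−(t−2020)} (c_t/c_{2020})^{−eta}` with packaged pairs
(0.01%, 1.02), (0.2%, 1.24), (0.5%, 1.42), (0.8%, 1.57) for near-term
rates 1.5/2/2.5/3%. Marginal damages difference the paired runs — which
share every sampled parameter (common random numbers, required for the
runs to be "otherwise identical") — and divide by the pulse mass in tCO2
(0.1 MtC × 44/12 × 1e6). Partial SC-CO2 values use one sector's marginal
damages with the *same* SDF path as the total, which makes sectoral
additivity exact; whether partials should share the total's discount path
is itself a convention, adopted here precisely to get exact additivity.
The pulse response is linear to well under 1% at these masses, so the
normalized SC-CO2 is pulse-size invariant.

All randomness flows from one master seed through named substreams
(scenario/climate/sealevel/damages/coastal), so draw k never changes when
more draws are added. Quantiles everywhere use the default
linear-interpolation convention (`stats::quantile` type 7). Dollar results
are 2020 USD; `to_2020_usd()` converts externally supplied base-year
values with an approximate implicit-GDP-deflator table.

## Problem sizes and numerical choices

Default runs use 184 countries, 281 annual steps (2020–2300), a 1750 spin-up,
and 500 coastal segments; tests and examples use 5–20 countries and
10–50 segments, and the calibration checks use 10,000 world-level draws
(vectorized, seconds). A full 100-draw Monte Carlo with defaults runs in
well under two minutes on one core. Tolerances: carbon conservation 1e-9
GtC/step (achieved: ~1e-13); alpha root 1e-7 yr on the response;
temperature equilibrium checks 1e-4 K; sectoral additivity 1e-9 relative
(achieved: exact in floating point); GEV tail integrals on a 5 cm grid
capped at 30 m (tail mass beyond the cap is negligible for the packaged
parameter ranges).

## Known limitations

Synthetic mode demonstrates the engine, not the world: damage coefficients
are placeholders at plausible scale, the coastal exposure base is orders
of magnitude below the real one, and the climate/sea-level priors are
independent where calibrated ensembles are correlated. Headline SC-CO2
levels in synthetic mode are therefore illustrative; defensible levels
require the deposited data-mode inputs. Structural limitations shared with
the design: no ozone/aerosol chemistry beyond the exogenous series, no
equity weighting, no non-CO2 social costs, expected-utility discounting
only, and mortality damages uncapped.
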