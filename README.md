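# herbiwue

Herbarium-based inference of long-term plant gas-exchange responses to
rising atmospheric CO2.

Herbarium collections preserve two physiological archives on every dried
leaf: stomatal anatomy and the stable carbon isotope composition of the
bulk tissue. `herbiwue` turns per-specimen records of stomatal density
(*D*), pore length (*L*), guard-cell width, leaf δ13C, leaf mass per area
and nitrogen per area — collected across a century of CO2 rise — into
species-level response estimates with honest uncertainty. It is written
for plant ecophysiologists working with historical collections, and for
anyone who needs a tested reference implementation of the underlying
gas-exchange arithmetic.

## What it computes

* **Anatomical maximum stomatal conductance** from the diffusion equation

  g_smax = (d_w / v) · D · a_max / (p + (π/2)·√(a_max/π)),  a_max = πL²/8

  with pore depth *p* equal to the guard-cell width (`gsmax()`,
  `leaf_gsmax()`, `augment_gsmax()`).
* **Isotope-derived gas exchange**: discrimination
  Δ = (δ13C_air − δ13C_plant)/(1 + δ13C_plant/1000), the C3 model
  Δ = a + (b − a)·c_i/c_a (a = 4.4‰, b = 27‰), and
  iWUE = c_a(1 − c_i/c_a)/1.6 (`specimen_iwue()`, `augment_iwue()`).
* **A specimen-parameterised photosynthesis simulation**: Vcmax,25
  predicted from leaf traits by a mixed-effects model, Arrhenius kinetics
  at leaf temperature, g_s = 0.51·g_smax, and the coupled Rubisco-limited
  FvCB + Fick system solved in closed form (`fit_vcmax_model()`,
  `eb_simulate()`).
* **Monte-Carlo propagation of intraspecific variability**: 10,000
  multivariate-normal draws of each species' g_smax-vs-CO2 regression
  coefficients, pushed through the simulation to put quantile confidence
  intervals on ΔiWUE/Δc_a, ΔA/Δc_a and Δg_s/Δc_a
  (`mc_species_responses()`).
* **Trend statistics**: OLS slopes with t-based CIs, relative sensitivity
  (% per 100 ppm at a 300-ppm reference), binned one-way ANOVA, a
  two-predictor variance partition, and RMSE between simulated and
  empirical slopes (`trend_table()`, `relative_sensitivity()`, ...).
* **Phenotypic-space comparison** of communities in (log a_max, log D):
  100×100 kernel-density grids and the Jensen–Shannon divergence
  (`density_grid()`, `jsd()`, `community_overlap()`,
  `iso_gsmax_contours()`).
* **A calibrated synthetic herbarium community** (five species, 246
  specimens, 1927–2015) so the full pipeline is testable without
  restricted specimen data (`generate_community()` and friends), plus a
  stage-oriented pipeline runner with a hashed manifest
  (`run_pipeline()`).

## Worked example

```r
library(herbiwue)

atm    <- generate_atmosphere()                      # ~305 -> ~400 ppm, 1927-2015
leaves <- generate_community(atmosphere = atm, seed = 42)
leaves <- augment_gsmax(leaves)                      # a_max, g_smax per leaf
leaves <- augment_iwue(leaves, atm)                  # Delta, ci/ca, iWUE per leaf

trend_table(leaves, "iwue")[, c("species", "slope", "p", "rel_sensitivity")]
#>                      species   slope        p rel_sensitivity
#> 1      Amaroria soulameoides  0.1040 9.43e-03           19.29
#> 2 Astronidium confertiflorum  0.2003 9.92e-06           49.89
#> 3           Dillenia biflora  0.1102 3.93e-03           26.22
#> 4      Elattostachys falcata -0.0494 2.68e-01           -8.44
#> 5              Gnetum gnemon  0.1701 1.70e-05           47.11
#> 6                   combined  0.0817 2.24e-04           17.20
```

Four species show a significant iWUE rise (slopes in µmol mol⁻¹ per ppm
of CO2; `rel_sensitivity` is the percentage change per 100 ppm relative
to the fitted value at 300 ppm); the non-responder archetype
(*E. falcata*) does not. Propagating each species' g_smax regression
uncertainty through the simulation:

```r
model <- fit_vcmax_model(generate_vcmax_training(seed = 42))
mc    <- mc_species_responses(leaves, atm, model, n_draws = 10000, seed = 42)
subset(mc, response == "eta2")[, c("species", "mean", "lo", "hi")]
#>                       species      mean       lo        hi
#> 3       Amaroria soulameoides -0.002410 -0.00313 -0.001690
#> 6  Astronidium confertiflorum -0.000167 -0.00119  0.000868
#> 9            Dillenia biflora -0.001215 -0.00163 -0.000809
#> 12      Elattostachys falcata  0.000216 -0.00107  0.001510
#> 15              Gnetum gnemon  0.000495 -0.00011  0.001120
```

The simulated stomatal-conductance response (`eta2`, mol m⁻² s⁻¹ per
ppm) declines credibly — 95 % interval entirely below zero — only for the
two species whose stomatal density actually falls with CO2; for the
others the interval straddles zero. That is the package's core point:
with intraspecific variability propagated, apparent responses separate
from noise species by species.

See `vignettes/herbarium-co2-inference.Rmd` for the model, its
assumptions, the generator calibration and the numerical choices.

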