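---
title: "Inferring long-term CO2 responses from herbarium stomatal and isotope traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring long-term CO2 responses from herbarium stomatal and isotope traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbiwue)
```

## The problem

Herbarium sheets are the only widely available archive of leaf material
spanning the last century of anthropogenic CO2 rise. Two leaf properties
preserved on a dried specimen carry a gas-exchange signal:

* **Stomatal anatomy** — stomatal density $D$, pore length $L$ and
  guard-cell width (used as pore depth $p$) — sets the *anatomical maximum
  stomatal conductance*,
  $$g_{smax} \;=\; \frac{d_w}{v}\,
    \frac{D\,a_{max}}{p + \frac{\pi}{2}\sqrt{a_{max}/\pi}},
    \qquad a_{max} = \pi L^2/8,$$
  with $d_w = 2.49\times10^{-5}\,$m$^2\,$s$^{-1}$ the diffusivity of water
  vapour and $v = 2.24\times10^{-2}\,$m$^3\,$mol$^{-1}$ the molar volume of
  air, both at 25 °C. `gsmax()` evaluates this in SI units and returns
  mol m$^{-2}$ s$^{-1}$.
* **Bulk-leaf $\delta^{13}$C** records time-integrated discrimination
  $\Delta_{plant} = (\delta^{13}C_{air} - \delta^{13}C_{plant}) /
  (1 + \delta^{13}C_{plant}/1000)$, which under the simple C3 model
  $\Delta = a + (b-a)\,c_i/c_a$ (diffusion fractionation $a = 4.4$ ‰,
  net carboxylation fractionation $b = 27$ ‰ for bulk leaf material)
  yields $c_i/c_a$ and hence the intrinsic water-use efficiency
  $\mathrm{iWUE} = c_a(1 - c_i/c_a)/1.6$.

Regressing these quantities on the ambient CO2 of each specimen's
collection year gives per-species response slopes
($\Delta\mathrm{iWUE}/\Delta c_a$, $\Delta g_{smax}/\Delta c_a$,
$\Delta D/\Delta c_a$, ...). The difficulty is that herbarium trait data
are extremely noisy — intraspecific variation of tens of percent around
any fitted trend, plus uneven collection effort across decades — so point
estimates of response slopes can mask or fabricate species differences.
The package's central purpose is to carry that intraspecific uncertainty
*through* a mechanistic simulation, rather than discarding it.

## The simulation engine

`eb_simulate()` implements an empirical–biochemical chain, applied
specimen by specimen:

1. **Vcmax from functional traits.** A mixed-effects model on transformed
   scales,
   $$\ln V_{Cmax,25} = a\,\tfrac{1}{N_{area}} + b\,\ln SLA +
     c\,\tfrac{\ln SLA}{N_{area}} + d + (1\,|\,\text{species}),$$
   is fitted to a gas-exchange training set (`fit_vcmax_model()`, backed
   by `lme4`) and evaluated for each herbarium leaf from its LMA and
   nitrogen per area (`predict_vcmax25()`). Training-set species receive
   their random intercept; unseen species the fixed part only.
2. **Kinetics at leaf temperature.** $V_{Cmax}$, $K_C$, $K_O$ and
   $\Gamma^*$ are moved from 25 °C to the operational leaf temperature
   (29 °C by default) with Arrhenius functions using the Bernacchi (2001)
   constants ($K_{C,25} = 404.9$ µmol mol$^{-1}$,
   $K_{O,25} = 278.4$ mmol mol$^{-1}$, $\Gamma^*_{25} = 42.75$ µmol
   mol$^{-1}$, $O = 210$ mmol mol$^{-1}$); day respiration is
   $R_d = 0.015\,V_{Cmax}$. All constants live in `eb_constants()` and can
   be overridden there.
3. **Conductance chain.** Operational stomatal conductance is taken as a
   fixed fraction of the anatomical maximum, $g_s = 0.51\,g_{smax}$ (a
   field-calibrated ratio that is approximately stable on developmental
   timescales); $g_c = g_s/1.6$; the boundary layer
   ($g_{cb} = 2$ mol m$^{-2}$ s$^{-1}$) acts in series,
   $g_t = g_c g_{cb}/(g_c + g_{cb})$. Mesophyll conductance is treated as
   infinite and ternary interactions between water and CO2 fluxes are not
   modelled (they shift $c_i$ by roughly 2 %).
4. **Coupled solution.** Substituting Fick's law $c_i = c_a - A/g_t$ into
   the Rubisco-limited rate
   $A_c = V_{Cmax}(c_i-\Gamma^*)/(c_i+K_m) - R_d$ gives a quadratic in
   $A$; `solve_assimilation()` takes the root with admissible
   $c_i \in (0, c_a)$ — provably unique for valid inputs — and both
   equations are satisfied to $10^{-9}$. Rubisco limitation is assumed
   throughout because under saturating light it holds at ambient CO2 of
   400 µmol mol$^{-1}$ and below; the RuBP-regeneration rate `aj_rate()`
   is provided for completeness but is not on the default path.

Simulated iWUE is $A/g_s$ by definition, so the engine's iWUE identity is
exact rather than approximated through $(c_a - c_i)/1.6$.

## Propagating intraspecific variability

The statistical layer (`mc_species_responses()`) treats the species-level
regression of specimen $g_{smax}$ on ambient CO2 as an uncertain object,
not a point estimate:

1. OLS fit $g_{smax} = \beta_1 + \beta_2 c_a$ per species
   (`fit_gsmax_regression()`); specimens are the empirical unit.
2. 10,000 coefficient pairs drawn from the multivariate normal sampling
   distribution of $(\hat\beta_1, \hat\beta_2)$
   (`sample_coefficients()`, backed by `MASS::mvrnorm`).
3. Each draw defines an annual $g_{smax}(t)$ trajectory over the
   atmosphere series; draws that dip non-positive are floored at
   1 mmol m$^{-2}$ s$^{-1}$ and counted, keeping the ensemble size fixed
   without rejection bias.
4. The engine runs every draw-year (vectorised closed-form quadratic), and
   each draw's annual iWUE, $A$ and $g_s$ series are regressed on CO2.
5. The per-draw slopes $\delta_2$, $\gamma_2$, $\eta_2$ are summarised by
   their mean and equal-tailed 2.5/97.5 percentile interval.

Because the only stochastic input is the coefficient draw, the width of
the resulting intervals is exactly the part of the simulation uncertainty
attributable to intraspecific $g_{smax}$ variation (plus sampling gaps).
A zero coefficient covariance provably collapses the intervals to zero
width, which the test suite asserts. The ensemble is re-hosted here on the
annual-resolution engine above; at annual resolution the daily-to-annual
aggregation step of coupled biogeochemical hosts is vacuous, which is the
one resolution deviation of this implementation.

## Phenotypic space

`density_grid()` estimates a Gaussian-kernel density of specimens in
$(\log a_{max}, \log D)$ on a 100×100 grid (`MASS::kde2d`,
normal-reference bandwidths) and normalises cells to probabilities.
`jsd()` computes the Jensen–Shannon divergence
$\mathrm{JSD} = \frac12 KL(p\|m) + \frac12 KL(q\|m)$, $m = (p+q)/2$, with
base-2 logarithms, so 0 means complete overlap and 1 complete divergence.
A formulation of this divergence sometimes appears in print without the
factor 2 inside the logarithm (equivalently, with $m$ replaced by
$p + q$); that form evaluates to $-1$ for identical distributions and
violates the $[0,1]$ bounds, so this package deliberately implements the
standard mixture form. Zero cells follow $0\log 0 = 0$, and a cell empty
in one community only contributes finitely through the mixture.
`iso_gsmax_contours()` draws the lines of equal conductance implied by
the diffusion equation for overlaying on trait clouds; its default
pore-depth rule sets the guard-cell width to half the pore length implied
by the elliptical pore.

## The synthetic community

Because curated per-specimen herbarium datasets are rarely redistributable,
`generate_community()` provides a calibrated synthetic stand-in used by
the tests and the acceptance script. It is not a dial: its defaults *are*
the study conditions the package targets.

* Five species, 246 specimens (50/50/49/49/48), collection years 1927–2015
  with a linearly increasing effort profile (early decades under-sampled).
* Atmosphere: monotone piecewise-exponential CO2 rise ~305.6 → ~399.6 ppm
  with linearly declining $\delta^{13}C_{air}$ (−6.70 → −8.44 ‰). The
  bundled CSV (`inst/extdata/atmosphere_1927_2015_synthetic.csv`) is a
  smooth synthetic reconstruction anchored at those endpoints, to be
  replaced by a measured series for real analyses.
* Two *responders* whose stomatal density declines at −3.52 and −0.76
  mm$^{-2}$ ppm$^{-1}$. Their anatomy (pore length 5.0/6.5 µm, guard-cell
  width 3.4/4.6 µm, density 740/250 mm$^{-2}$ at 300 ppm) was solved
  analytically so those density trends propagate through the conductance
  equation to $g_{smax}$ trends of −6.2 and −1.7 mmol m$^{-2}$ s$^{-1}$
  ppm$^{-1}$, the per-stoma conductance factor being
  $k = (d_w/v)\,a_{max}/(p + \frac{\pi}{2}\sqrt{a_{max}/\pi})$ and the
  emergent slope $k \cdot \Delta D/\Delta c_a$.
* Constant $c_i/c_a$ targets of 0.728/0.776/0.776/0.792 for four species,
  giving iWUE slopes of $(1-r)/1.6$ = 0.17/0.14/0.14/0.13 µmol mol$^{-1}$
  ppm$^{-1}$; the fifth species' target drifts upward at
  $(1-r_0)/404$ ppm$^{-1}$ so that its iWUE stays flat while its pore
  length creeps up by 0.002 µm ppm$^{-1}$ — the non-responder archetype.
  Leaf $\delta^{13}$C is back-computed by inverting the discrimination
  chain at each specimen's year and adding 0.8 ‰ Gaussian noise, within
  the 2–4 ‰ within-year spreads such collections show.
* Intraspecific noise is multiplicative log-normal with unit mean:
  relative SD 0.12 for density, 0.06 for pore length (0.12 for pore
  area), 0.04 for guard-cell width and 0.10 for LMA and N$_{area}$. The
  implied 95 % residual bands — ±26 % for density and pore area, ±40 %
  for $g_{smax}$ — sit inside the ±25–50 % interval reported for such
  herbarium trait data. Species-mean LMA/N$_{area}$ were chosen so the
  trait model yields Vcmax$_{,25}$ of roughly 55/50/48/33/35 µmol m$^{-2}$
  s$^{-1}$, placing simulated assimilation near the species' field-measured
  9–15 µmol m$^{-2}$ s$^{-1}$.
* Sample sizes and noise were fixed by a design-time power analysis so
  that the qualitative response taxonomy is statistically recoverable:
  the ensemble $\eta_2$ intervals exclude zero for the two responders
  (expected |t| ≈ 5.3 and 3.4) and include zero for the others
  (|t| ≤ 0.6).

What the generator does *not* emulate: real covariance between traits
(noise is independent across traits), climate-driven interannual isotope
variation (the MAP column is pure white noise, so the iWUE variance
partition attributes ~100 % to CO2 by construction), measurement error
structure, or phylogenetic signal. Passing tests therefore demonstrate
that the estimators recover known structure under realistic noise levels
— not that any particular field dataset satisfies the model.

## Numerical and design choices

* Quadratic root selection: the smaller root is the physical one; the
  solver verifies $c_i < c_a$ and errors otherwise. An independent
  bisection oracle agrees to $|\Delta A| < 10^{-6}$ over 1,000 random
  parameterisations in the tests.
* Out-of-range $c_i/c_a$ (outside $[0,1]$, which isotopic noise produces)
  is returned flagged, never clamped — downstream regressions should see
  the scatter.
* Mixed-model estimation is by REML; the optional fixed-vs-mixed model
  comparison refits by full maximum likelihood before comparing AIC.
  A single-species training set falls back to fixed effects with a
  warning.
* The two-predictor variance partition uses order-averaged incremental
  $r^2$ (the two-predictor case of dominance analysis): well-defined,
  label-symmetric, and summing to the full-model $r^2$.
* Relative sensitivities are percentages of the fitted value at 300 ppm
  per 100 ppm of CO2.
* Missing values are absences (`NA`), never zeros; validation is
  report-only and idempotent; units are fixed per column with no
  auto-detection.
* Problem sizes used by the test-suite: 100-seed slope-recovery sweeps of
  the full 246-specimen community, 10,000-draw ensembles for the
  Monte-Carlo contracts, and 1,000 random solver parameterisations —
  chosen as the smallest sizes at which the binomial/Monte-Carlo noise of
  each check is negligible relative to its tolerance.

## Known limitations

* The engine assumes Rubisco limitation, saturating light, non-limiting
  VPD, infinite mesophyll conductance and a fixed $g_s/g_{smax}$ ratio;
  all four weaken under shade, drought or high CO2 (> ~400 µmol mol$^{-1}$).
* The trait model is an empirical transfer function; applying it to
  centuries-old material assumes the Vcmax–N$_{area}$–SLA relationship is
  time-stable.
* Annual resolution: no daily meteorology, canopy structure, or soil
  feedbacks. The Monte-Carlo layer is deliberately model-agnostic and can
  re-host on a daily-resolution simulator without modification.
* The atmosphere table bundled here is a synthetic reconstruction;
  substitute measured annual records for real analyses.
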