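---
title: "Modelling leaf-to-canopy carbon isotope discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leaf-to-canopy carbon isotope discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocanopy)
```

## What the package models

C3 plants discriminate against ¹³CO₂ during photosynthesis, so the carbon
laid down in leaves and tree rings is isotopically lighter than the air it
came from. The strength of that discrimination, Δ¹³C, is controlled mainly
by the ratio of leaf-internal to ambient CO₂ (ci/ca), which in turn is set
by stomatal behaviour. Δ¹³C chronologies from tree-ring cellulose therefore
carry a decadal record of how forests have adjusted their stomata — and
their intrinsic water-use efficiency, iWUE = (ca − ci)/1.6 — as CO₂, air
temperature and atmospheric dryness changed.

`isocanopy` couples a Farquhar-type C3 photosynthesis scheme to four
alternative closures for leaf-internal CO₂, a layered soil-water stress
factor, a sunlit/shaded canopy upscaling, and three formulations of Δ¹³C.
Around that simulation core it provides the observation-side processing
needed to confront predictions with isotope chronologies and
eddy-covariance fluxes, the robust statistics used for that comparison, and
seeded synthetic-forcing generators so the whole pipeline runs and is
tested without any external data.

## Leaf model

Gross assimilation is the smoothed minimum W of a RuBisCO-limited rate
`A_C = Vcmax (ci − Γ*)/(ci + K)` and a light-limited rate
`A_J = J (ci − Γ*)/(4ci + 8Γ*)`, where J follows a non-rectangular
hyperbola in absorbed light and Jmax. Γ* (the CO₂ compensation point
without dark respiration) and the effective Michaelis constant
K = Kc(1 + O/Ko) follow Arrhenius responses referenced to 25 °C and
99.1 kPa. Two kinetic constant sets are shipped and never mixed within one
evaluation: an intercellular-CO₂-based set (Bernacchi et al. 2001;
Γ*₂₅ = 42.75 µmol mol⁻¹) for model variants that treat mesophyll
conductance as infinite, and a chloroplast-based set (Bernacchi et al.
2002; Γc*₂₅ = 37.43 µmol mol⁻¹) for the finite-mesophyll variants. All
adopted constants are listed with sources in
`inst/extdata/kinetic_constants.csv`; equally citable variants of these
constants differ by a few percent, which propagates directly into Γ* and K,
so the file is the single place to swap them.

Net assimilation applies the soil-water stress factor to the net rate,
`A_n = (W − Rd) β_soil`. This convention (rather than stressing only the
respiration term) is chosen deliberately: it makes canopy GPP
= 0.012 (A_can + R_dc β_soil) collapse to 0.012 ΣWβ, keeping the carbon
bookkeeping internally consistent from leaf to canopy. Dark respiration is
Rd = f_d·Vcmax at the same leaf temperature; Vcmax and Jmax use a peaked
(entropy-term) Arrhenius response. Leaf temperature is taken equal to air
temperature — there is no leaf energy balance — but `T_leaf` is a separate
forcing column so users can supply their own.

## The four ci closures

At each timestep the closure determines ci (or chloroplastic cc), the
Farquhar rates are evaluated there, and stomatal conductance follows from
the diffusion relation gsc = A_n/(ca − ci).

* **jacobs** — ci interpolates between Γ* and ca as a linear function of
  the specific humidity deficit, closing fully at `dq_crit`.
* **medlyn** — ci = ca·g1/(g1 + √D). The slope g1 carries units kPa^0.5,
  which fixes the square-root dependence on vapor pressure deficit.
* **leuning** — the canonical conductance model
  gsc = g0 + a1·A_n/((ca − Γ*)(1 + D/D0)). For g0 = 0 it has an
  assimilation-independent closed form; with g0 > 0 the coupled system is
  solved by a bracketed scalar root search on ci (relative tolerance 1e−8,
  bracket (Γ*, ca)), verified in the tests against a grid-scan oracle.
  Parameter combinations with a1 ≤ 1 + D/D0 cannot sustain a positive
  CO₂ gradient; they are flagged degenerate and pinned at Γ*.
* **prentice** — least-cost optimality:
  ci = Γ* + (ca − Γ*)·ξ/(ξ + √D) with ξ = √(β(K + Γ*)/1.6η*). D, K and Γ*
  enter in Pa, so conversions from mole fraction use the ambient pressure;
  the relative viscosity η* is fixed at 1. The cost ratio defaults to
  β = 146.
* **prentice-cc** — the finite-mesophyll variant predicting cc with
  ξc = √(βc(Kc + Γc*)/(1.6η*(1 + gsc/gm))) and chloroplast-based kinetics.
  The gsc/gm ratio is a fixed PFT parameter (default 0.25). Given cc, the
  fixed ratio implies ci = (cc + r·ca)/(1 + r). The default
  βc = 218.6 was calibrated once, by the closed-form inversion in
  `calibrate_beta_cost_c()`, so that the chloroplastic closure reproduces
  the infinite-gm closure's ci at 25 °C, 99.1 kPa, D = 1 kPa and
  ca = 400 µmol mol⁻¹; it is a package default, not a fitted quantity.

At night (PPFD = 0) the closures are bypassed: A_n = −Rd·β_soil, ci is set
to ca, and conductance to a configurable cuticular minimum (`g_night`,
default 0.003 mol m⁻² s⁻¹). The closures themselves are silent about
nighttime behaviour, so this is an explicit package convention.

## Soil water stress

Each of the (default 14) soil layers gets a piecewise-linear stress factor:
1 above θ_upp = θ_w + (1 − p₀)(θ_c − θ_w), 0 at the wilting point, linear
between. The onset parameter p₀ = 0.4 delays stress below field capacity
and applies identically to every layer. β_soil is the root-mass-weighted
mean of the layer factors. The soil moisture series itself is an input; the
synthetic generator provides a seasonal sinusoid with AR(1) noise per
layer, because a full soil-hydrology scheme is outside the package's scope.

## Canopy upscaling and water fluxes

The canopy is divided into n (default 10) equal-LAI layers. At each layer
midpoint the sunlit fraction is exp(−k_b·L) with beam extinction
k_b = 0.5/cos(zenith); shaded leaves receive an exponentially attenuated
diffuse flux (extinction 0.7, diffuse fraction 0.3 of the incident flux).
Layer-midpoint (rather than layer-top) cumulative LAI is a documented
choice. Leaf quantities are summed as
X_c = Σ[f_sun·X_sun + (1 − f_sun)·X_shade]·LAI/n, which is exact for a
homogeneous canopy. GPP is reported internally in kg C m⁻² s⁻¹ and
converted to g C m⁻² day⁻¹ at the reporting layer.

The canopy water conductance converts the molar conductance to a velocity
through the ideal-gas molar volume: G_sw = 1.6·(R·T_s/P)·A_can/(ca − ci).
The division by pressure is required for dimensional consistency of the
mol m⁻² s⁻¹ → m s⁻¹ conversion and is therefore explicit here. Latent heat
and transpiration follow the standard aerodynamic forms; their surface
inputs (ψ, ρ, r_a, wet/vegetated fractions, specific humidities) are
forcing-level inputs with defaults ψ = 1, f_a = 0, f_v = 1, because no
surface energy balance is modelled.

## Discrimination models

Three nested formulations are provided:

* **simple** — Δ = a + (b′ − a)·ci/ca with a = 4.4‰, b′ = 27‰; the lumped
  slope absorbs the neglected mesophyll and photorespiration terms.
* **photo** — Δ = a + (b̄ − a)·ci/ca − f·Γ*/ca with b̄ = 28‰, f = 12‰;
  Γ* enters as a mole fraction, pressure-consistent with ca.
* **full** — Δ = a(ca − ci)/ca + b·cc/ca − f·Γc*/ca + a_m(ci − cc)/ca with
  b = 30‰ and a_m = 1.8‰; `delta13c_full()` returns the four terms, which
  sum to Δ exactly.

For model intercomparison a `b_carbox = "b30"` switch replaces the lumped
27/28‰ slopes with 30‰ in all variants, so differences between variants
then isolate the photorespiratory and mesophyll terms; the lumped defaults
are appropriate for site-level comparison against observations.

Two trend calculators quantify how these terms move under environmental
change. `photorespiration_trend()` propagates an air-temperature trend
through the Arrhenius response of Γ*: with 0.029 K yr⁻¹ over 17–25 °C
leaves it yields a central Γ* trend of ≈0.053 ppm yr⁻¹ (half-range ≈0.01),
and combines it with a CO₂ ramp through −f·Γ*/ca. The central value is
reported as the mean over the temperature range, with the half-range
attached, since either could be meant by a "± range" on such a number.
`k2017_mesophyll_contribution()` evaluates the mesophyll term
−(b − a_m)(A/gm)/ca at two CO₂ endpoints with prescribed assimilation
growth (a helper converts "45% per CO₂ doubling" to a linear fraction per
interval) and returns the contribution per ppm; holding gm at
0.2 mol m⁻² s⁻¹ over 330→377 ppm gives ≈+0.006‰ ppm⁻¹, while letting gm
fall to 0.19 or 0.18 gives ≈+0.002 and ≈−0.003‰ ppm⁻¹ — the sign of the
mesophyll contribution hinges on a few-percent change in gm.

## Observation processing

`delta_from_d13c()` converts plant δ¹³C to Δ¹³C against the atmospheric
δ¹³CO₂ of the same year, after subtracting a post-photosynthetic
fractionation f_post (default 2.1‰ between bulk leaf and α-cellulose;
SD ≈ 1.2‰ in the literature). Per-site apparent f_post values estimated at
eddy-covariance sites are shipped in `inst/extdata/fpost_sites.csv`
(network means 4.05‰ and 2.2‰); `apparent_fpost()` reproduces the
underlying leaf/wood arithmetic including the 1.1‰ bulk-wood correction.
Matching of the atmospheric series is an exact-year join — no
growing-season correction of δ¹³CO₂ is applied, a known simplification.

Chronology selection keeps records with ≥25 non-missing years inside
1979–2012 (count of years with data, not contiguous span). Flux screening
applies, in order: good-quality flags; D ≥ 0.01 kPa; daytime only (the
daytime flag when present, else PPFD > 0); and exclusion of calendar days
with precipitation together with the following calendar day. Retention
equals the row-by-row conjunction of all rules, which the tests assert.

## Statistics

Trends are Theil–Sen slopes (median of all pairwise slopes, median-based
intercept) with Mann–Kendall significance at α = 0.05 via
`stats::cor.test(method = "kendall")`. Interannual variability is the
sample SD (n−1) of residuals about the robust line; since an additive
constant cancels, the intercept convention is immaterial and is documented
rather than load-bearing. Taylor statistics (r, normalized SD, centered
RMSE) satisfy the law-of-cosines identity to machine precision. Climate
scores are per-cell means over half-open bins ([lo, hi); default widths
5 °C, 0.4 kPa, 0.1 in β_soil) with cells of ≤20 points masked. Variance
partitioning standardizes response and drivers and averages sequential R²
increments over all driver orderings, a relative-importance decomposition
whose shares are permutation-invariant by construction and sum to R²; it
is one reasonable choice among several, made explicitly because no single
convention dominates.

## Synthetic forcing: what it does and does not emulate

The generators exist so that every pipeline stage is exercised end-to-end,
deterministically, from a scenario plus one integer seed. `generate_met()`
builds half-hourly PAR from solar geometry, seasonal + diurnal + trending
temperature, VPD coupled to temperature through a Magnus saturation vapor
pressure (Alduchov–Eskridge coefficients) with stochastic
relative-humidity anomalies, a linear CO₂ ramp (default 1.72 ppm yr⁻¹ from
337 ppm in 1979), and daily rain occurrence.
`generate_isotope_network()` inverts the Δ¹³C→δ¹³C conversion from
prescribed trends, variability and f_post offsets, returning a truth table
for recovery tests. `generate_flux_record()` plants known counts of bad
flags, sub-threshold VPD, night rows and rain days so the post-screening
row count is computable in closed form.

These series have realistic shapes and magnitudes but idealized structure:
no weather autocorrelation beyond the AR(1) soil term, no drought
episodes, no covariance between cloudiness and VPD, 365-day years, and no
species- or site-level ecology in the isotope network. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
recover known structure, not that the model reproduces any particular
site's climate or chronology.

## Numerical choices and problem sizes

All closures are closed-form except Leuning with g0 > 0 (bracketed root
solve, tolerance 1e−8 relative, ≤100 iterations; non-bracketing residuals
fall back to the g0 = 0 form). Degenerate inputs are errors, not silent
fixes: β_soil outside [0, 1], wilting point above field capacity,
ci = ca with nonzero assimilation, all-zero GPP weights. Bin edges are
half-open so boundary points go to the upper cell. The test suite runs the
coupled model at reduced sizes chosen to probe every code path — one to
six simulated years at 2–6 h timesteps with 3–5 canopy layers, a 100-site
isotope network, trend oracles up to 200 points — sizes at which the
brute-force oracles (pairwise-slope enumeration, closure grid scans) are
exact and fast.

## Known limitations

No leaf energy balance, boundary-layer conductance, triose-phosphate
limitation, C4 pathway, nitrogen-driven Vcmax profiles (an exponential
decay hook exists but defaults off), dynamic mesophyll conductance,
isotopic fractionation during mitochondrial respiration, or chronology
detrending. PFT parameter defaults are literature-typical stand-ins, not a
calibrated set; conclusions about any real site require user-supplied
parameters and forcing.
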