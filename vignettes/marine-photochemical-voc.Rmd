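---
title: "Modelling photochemical VOC emissions from the sea-surface microlayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling photochemical VOC emissions from the sea-surface microlayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlvoc)
```

## The process being modelled

The uppermost micrometres of the ocean are almost ubiquitously covered by a
film of surface-active organic compounds — the sea-surface microlayer (SML).
Sunlight drives abiotic photochemistry in this film, producing volatile
organic compounds (VOCs) such as isoprene and oxygenated species without any
direct biological emission. `smlvoc` scales laboratory measurements of this
interfacial photochemistry to the global ocean and asks two questions: where
and when is the abiotic source significant, and what can the emitted vapours
contribute to organic aerosol mass in the marine boundary layer (MBL)?

The pipeline has four stages, each exposed as ordinary functions on
`monthly_field` objects (12 × nlat × nlon arrays with units and a missing
mask, on a 1° × 1° global grid).

## Stage 1: where microlayers persist

SML presence is controlled by biology (surfactant supply) and wind (film
disruption by breaking waves):

* **Trophic state** from net primary production (NPP, g C m⁻² day⁻¹):
  oligotrophic below 0.4, mesotrophic between 0.4 and 1.2, eutrophic above
  1.2. The classification thresholds are open intervals on the outer
  classes; cells exactly at 0.4 or 1.2 are assigned to the mesotrophic
  class. This boundary convention is an implementation decision — the
  defining inequalities are strict only for the outer classes — and is
  documented here so that classifications are bit-reproducible.
* **Surfactant concentration** by trophic state: 320, 502 and
  663 µg Teq L⁻¹ (Triton-X equivalents) for oligo-, meso- and eutrophic
  waters, the mean values observed in the field.
* **Wind limit**: cells whose monthly-mean 10-m wind strictly exceeds the
  limit are film-free. Field evidence brackets the limit between 8 and
  13 m s⁻¹, so all calculations support limits of 8, 10 and 13; wind exactly
  at the limit counts as covered (the defining criterion is "exceeding").

## Stage 2: the daily photochemical emission potential

On covered ocean cells the potential is the product

$$\mu_{\mathrm{photo}} = t_{\mathrm{sun}} \cdot \mathrm{UV}_{a,b} \cdot
F_{\mathrm{surfactant}} \cdot k_g,$$

and exactly zero elsewhere. The factors:

* $t_{\mathrm{sun}}$ — day length in seconds, computed from the standard
  sunrise equation at mid-month (declination
  $\delta = 23.44° \sin(2\pi(284+n)/365)$, hour angle
  $\cos\omega_0 = -\tan\phi\tan\delta$ clamped for polar day/night).
  Because some UV climatologies already integrate irradiance over the day,
  `photochem_config(multiply_t_sun = FALSE)` removes this factor; the
  default multiplies it, matching the potential's definition. This switch is
  the honest answer to an ambiguity we could not resolve: whether a given UV
  product is a mean daytime rate or a daily dose is a property of the input,
  not of the model.
* $\mathrm{UV}_{a,b}$ — surface irradiance summed over 280–400 nm, in
  mW cm⁻², treated as a single scalar (no spectral resolution).
* $F_{\mathrm{surfactant}} = \ln(c)/\ln(c_{\max})$ — photochemical VOC
  production decays logarithmically with surfactant concentration;
  normalising to the eutrophic mean (663 µg Teq L⁻¹) makes $F$ a fraction in
  (0, 1]. At the oligotrophic mean it removes ≈11% of the emissions, at the
  mesotrophic mean ≈4%.
* $k_g = (8.2 + 0.014\,U_{10}^3)/(8.2 + 0.014\,U_{\mathrm{lab}}^3)$ — a
  cubic wind-speed enhancement of air–sea gas transfer normalised to the
  laboratory flow speed $U_{\mathrm{lab}} = 5.31\times10^{-2}$ m s⁻¹ at
  which the production rates were measured. The additive constant keeps
  transfer non-zero at zero wind; at the 13 m s⁻¹ limit the factor reaches
  ≈4.75.

The unit of µ_photo, mW s cm⁻² day⁻¹, is kept verbatim from its definition
even though it is dimensionally a daily UV dose times dimensionless factors:
it cancels exactly against the laboratory production rates in stage 3.

## Stage 3: species fluxes and global totals

Ambient fluxes are the laboratory production rate scaled by the potential,
$\mathrm{VOC}_{\mathrm{ambient}} = \mathrm{VOC}_{\mathrm{lab}} \cdot
\mu_{\mathrm{photo}}$ (molecules cm⁻² day⁻¹). The registry ships isoprene
with its measured range (3.71–6.19 × 10⁷ molecules mW⁻¹ s⁻¹). For acetone
and acetaldehyde only ambient flux ranges have been reported; their registry
entries are back-derived placeholders (flux range divided by a reference
potential of 5.67 × 10⁴ mW s cm⁻² day⁻¹) and are marked `back-derived` so
nobody mistakes them for measurements.

Global annual totals integrate the flux over ocean cell areas
($A = R^2 \Delta\phi \Delta\lambda \cos\phi$, spherical Earth of radius
6371 km) and a 365-day no-leap calendar — the natural choice for
climatological monthly means. Carbon totals weight each species by
$12.011\,n_C/M$. Regional means default to area weighting, with a flag to
disable, since the averaging convention of published regional values is not
stated.

## Stage 4: the boundary-layer box model

A well-mixed column of height $h$ receives a constant surface emission $E$
(molecules cm⁻² s⁻¹) of unsaturated VOC, instantaneously diluted. The
precursor is oxidised by OH with pseudo-first-order rate
$k = k_{\mathrm{OH}} c_{\mathrm{OH}}$, approaching the analytic steady state
$C_{ss} = E/(h k)$. Defaults: $c_{\mathrm{OH}} = 1.5\times10^6$ cm⁻³ and
$k_{\mathrm{OH}} = 1.0976\times10^{-10}$ cm³ molecule⁻¹ s⁻¹, a mean over
unsaturated compounds. The source listing of this constant carries a
positive exponent (10¹²) that is physically impossible — eight orders of
magnitude beyond the gas-kinetic collision limit — so the package uses the
10⁻¹² scale, which is the only reading consistent with the documented
steady state of the reference scenario (≈4 × 10⁸ cm⁻³, i.e. ≈16 ppt$_V$,
for $E = 4.1\times10^9$ cm⁻² s⁻¹ into 600 m).

Oxidation products are distributed over a ten-bin volatility basis set,
$\log_{10} C^*(300\,\mathrm{K}) = -3..6$ (µg m⁻³), with low-NOx alkene mass
yields $\alpha = \{0, 0, 0, 0.023, 0.044, 0.129, 0.375, 0, 0, 0\}$ aligned
with the bins in increasing volatility. Gas/particle partitioning is
equilibrium absorptive partitioning: particle fraction
$\xi_i = (1 + C^*_i/C_{\mathrm{abs}})^{-1}$ with the absorbing mass
$C_{\mathrm{abs}}$ solved self-consistently.

Numerical and convention choices:

* **Time stepping** — explicit Euler, default dt = 60 s, with a hard guard
  `dt·k < 0.1`; partitioning is re-equilibrated every step (assumed
  instantaneous relative to the chemistry). Halving dt changes 12-h outputs
  by well under 0.5%.
* **Partitioning solver** — the fixed point is found by bracketed root
  search (`uniroot` on $[C_{\mathrm{seed}}, C_{\mathrm{seed}} + \sum T_i]$)
  plus a fixed-point polish, to a relative residual of 10⁻¹⁰; per-bin mass
  $G_i + P_i$ is conserved exactly by construction. With no seed, the
  all-gas state is itself a solution; a condensed branch exists only when
  $\sum T_i/C^*_i > 1$, which for a single bin reduces to the closed form
  $C_{OA} = \max(0, T - C^*)$.
* **Primary aerosol** — the background POA (default 0.4 µg m⁻³, typical
  remote marine air) is non-volatile and, by default, does **not**
  participate in the absorbing mass; a 10⁻⁶ µg m⁻³ seed bootstraps
  condensation once products supersaturate. Setting
  `poa_in_absorbing_mass = TRUE` treats POA as an inert absorbing seed
  instead. POA emission schemes driven by SST/chlorophyll/wind exist in the
  literature but are not formulated here; any gridded background can be
  supplied through the same `monthly_field` interface.
* **Temperature** — bin volatilities shift from their 300 K reference by
  Clausius–Clapeyron, $C^*(T) = C^*(300)\,(300/T)\exp[(\Delta H/R)(1/300 -
  1/T)]$ with ΔH = 30 kJ mol⁻¹, switchable off; aging defaults to 12 h at
  15 °C.
* **Precursor mass** — oxidised number density converts to mass through
  `mw_voc` (default 68 g mol⁻¹, isoprene-like); the yields α are mass yields
  on the oxidised precursor mass.

A consequence worth understanding before interpreting box-model output:
with these yields, the bins that receive most of the product mass are the
*most* volatile occupied ones ($C^* = 10^2..10^3$ µg m⁻³), while the least
volatile occupied bin ($C^* = 1$ µg m⁻³ at 300 K) receives only
α = 0.023 of the oxidised mass. At remote-marine loadings of a few tenths of
µg m⁻³ no bin comes anywhere near saturation, so equilibrium partitioning
keeps essentially all products in the gas phase: in the reference scenario
above, the 12-h secondary-OA increase computed by `box_run()` with the
default conventions is of order 10⁻⁸ µg m⁻³, and no combination of the
convention switches documented here (absorbing-mass rule, precursor molar
mass up to ~150 g mol⁻¹, ΔH between 0 and 100 kJ mol⁻¹) raises it above
~10⁻² µg m⁻³. Substantially larger secondary-OA responses require either
yields concentrated at low volatilities or multigenerational aging that
moves product mass down the volatility axis — the latter is deliberately out
of scope (single-generation oxidation only, no ozone chemistry, no aerosol
microphysics), so box-model OA estimates from this package are conservative
lower bounds.

## The synthetic climatology

`synth_climatology()` generates seeded, physically plausible stand-ins for
the real inputs so that every stage is testable offline:

* **UV** peaks at the subsolar latitude (default 3 mW cm⁻² monthly-mean
  daytime irradiance), phase-shifts the seasonal cycle between hemispheres
  and is zero in polar night.
* **Wind** has westerly storm belts near ±50° whose default amplitude
  (9 m s⁻¹ over a 6.5 m s⁻¹ background) crosses all three SML limits, and
  equatorial doldrums.
* **NPP** is a smooth seeded surface with a coastal boost, quantile-mapped
  so that the classified trophic area fractions match configured targets
  (default 60/30/10% oligo/meso/eutrophic) by construction.
* The **ocean mask** is a set of pseudo-continent rectangles giving ≈70%
  ocean (3.57 × 10¹⁴ m²), close to the real ocean area.

Every generator is a pure function of its configuration: identical seeds
give bit-identical fields, and the session RNG stream is left untouched.
What the synthetic fields do *not* emulate: real shorelines and shelf seas,
cloud statistics in UV, synoptic wind variability below the monthly mean,
and the covariance between NPP blooms and wind seasons. Passing tests on
synthetic inputs therefore demonstrates the correctness of the machinery —
masking, composition, integration, monotonicity — not the realism of any
particular global number; published global totals require the real
climatologies, which enter through `read_monthly_netcdf()` with unit
checking and bilinear regridding to the 1° grid (weights renormalised over
valid stencil points so coastal cells survive interpolation from coarse
products).

## Problem sizes and costs

The package's own test suite runs the full 12 × 180 × 360 pipeline for the
coverage, potential and flux stages (a few seconds each), the reference
box-model scenario at dt = 60 s for 12 h (721 steps, under a second), and
per-cell box-model maps on small subsampled cell sets with dt = 300 s.
`soa_contribution_map()` exposes `stride` and `dt_s` so that global maps can
be traded between resolution and cost; a full-grid map at stride 1 runs tens
of thousands of independent column models and is best scheduled accordingly.

## Known limitations

* Laboratory production rates come from single-surfactant proxy systems;
  the ambient film is a complex mixture, so `VOC_lab` ranges carry that
  systematic uncertainty unreduced.
* SML coverage is a hard wind threshold on monthly means; film lifetime
  dynamics and slick thickness are not modelled.
* The box model is zero-dimensional with constant OH; no entrainment,
  deposition, NOx dependence beyond the fixed low-NOx yield set, ozone
  chemistry, multigenerational aging or particle microphysics.
* Back-derived registry entries (acetone, acetaldehyde) are placeholders
  suitable for sensitivity studies, not measurements.
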