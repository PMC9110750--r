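---
title: "Methods: two-leaf light-use-efficiency GPP modelling in tllue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-leaf light-use-efficiency GPP modelling in tllue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tllue)
```

## The model

`tllue` implements a two-leaf light-use-efficiency (TL-LUE) model of daily
gross primary production with CO₂-concentration regulation. The canopy is
divided into sunlit leaves, which receive both the direct beam and diffuse
sky radiation, and shaded leaves, which receive diffuse radiation only.
Each fraction converts its absorbed photosynthetically active radiation
(APAR, MJ m⁻² d⁻¹) into carbon with its own maximum light-use efficiency
(ε_msu for sunlit, ε_msh for shaded leaves; g C MJ⁻¹), down-regulated by
three multiplicative environmental scalars shared by both fractions:

* temperature `T_s(T) = (T−T_max)(T−T_min) / [(T−T_max)(T−T_min) − (T−T_opt)²]`,
  a rational response equal to 1 at the per-type optimum `T_opt` and 0 at the
  fixed limits `T_min = 273.15 K`, `T_max = 313.15 K`;
* water `W_s(VPD)`, a linear ramp from 1 at `VPD ≤ 0.93 kPa` to 0 at
  `VPD ≥ 4.1 kPa` (vapour pressure deficit is the only water-stress driver;
  there is no soil-moisture term by design);
* CO₂ `C_s = (C_i − Γ*) / (C_i + 2Γ*)`, where the intercellular CO₂ is
  `C_i = C_a · χ`, `χ = ξ/(ξ + √VPD)` with `ξ = √(356.51 K / 1.6 η*)`,
  `K = K_c (1 + P_o/K_o)` the combined Rubisco Michaelis–Menten coefficient
  (`P_o = 21 kPa`, relative water viscosity `η* = 0.8903`), and Γ*, K_c, K_o
  Arrhenius functions of air temperature with reference values 4.22, 39.97
  and 27480 at 298.15 K.

The radiation decomposition proceeds from the sky clearness index
`R = S/(S₀ cos θ)` (solar constant `S₀ = 1367 W m⁻²`): the diffuse fraction
of PAR is the quartic `0.7527 + 3.8453R − 16.316R² + 18.962R³ − 7.0802R⁴`,
sunlit leaf area is `LAI_su = 2cosθ(1 − e^(−LAI·Ω/2cosθ))` with clumping
index Ω, multiple scattering is `C = 0.07·Ω·PAR_dir(1.1 − 0.1·LAI)e^(−cosθ)`,
and diffuse PAR under the canopy attenuates as
`PAR_dif·exp(−0.5·Ω·LAI/cos θ̄)` with `cos θ̄ = 0.537 + 0.025·LAI`. Absorbed
PAR of the shaded fraction is `(1−α)[(PAR_dif − PAR_dif,u)/LAI + C]·LAI_sh`;
the sunlit fraction adds the projected direct beam
`PAR_dir·cos β/cos θ` with leaf angle β = 60° (cos β = 0.5), configurable.

## Temporal basis and units

The model runs at a daily step, but ε is defined per MJ of absorbed energy,
which forces an explicit energy integral. `tllue` uses a *daylength*
integral with a single representative solar geometry per day:

* `solar_cos_zenith()` returns the daytime mean of cos θ from standard
  solar-declination geometry (Cooper's declination approximation, averaged
  over the sunlit hour-angle range); `daylength_hours()` gives the matching
  day length. Polar night yields zero GPP.
* the 24-h mean shortwave flux in the forcing is rescaled to a daytime-mean
  flux (`× 86400 / daylength_s`) so that the clearness index compares a
  daytime flux with a daytime geometry, consistently;
* absorbed PAR in W m⁻² (daytime basis) is converted at the model-core
  boundary to MJ m⁻² d⁻¹ by multiplying with the daylength in seconds.

A 24-hour basis would be the alternative; it rescales both APAR and the
clearness index and is absorbed into ε during calibration, so calibrated
runs are insensitive to the choice, but fixed published efficiencies are
not. The choice is therefore stated here and used consistently everywhere
(forward model, calibration, synthetic truth).

PAR is obtained from shortwave radiation with a configurable factor
defaulting to 0.43 (literature range roughly 0.39–0.53). Flux-tower VPD
read from FLUXNET-style files (`VPD_F`, hPa) is converted to kPa;
photon-flux PAR (`PPFD_IN`, µmol m⁻² s⁻¹) is converted with
4.57 µmol J⁻¹ when present.

## Numerical choices and degenerate inputs

* `VPD` from specific humidity (Buck-type saturation formula with
  coefficient 0.61121 kPa at 0 °C) is floored at 0 for supersaturated air.
* The clearness index is clipped to [0, 1]; the daytime-mean geometry can
  push the raw ratio slightly above 1, outside the diffuse-fraction
  polynomial's calibrated domain.
* The diffuse fraction itself is clipped to [0, 1].
* `LAI_su` is capped at LAI (the exponential form can marginally exceed it
  for sparse canopies at high sun) so `LAI_sh ≥ 0`; the split then closes
  exactly.
* The multiple-scattering term is floored at 0 (its linear LAI factor goes
  negative above LAI = 11).
* At LAI = 0 both absorbed-PAR terms are defined as 0, bypassing the
  0/0 in the per-leaf diffuse gradient.
* `T_s` is defined as 0 at and beyond the temperature limits, where the
  rational form would leave [0, 1]; `C_s` is floored at 0 when
  `C_i ≤ Γ*`.
* The CO₂ chain is implemented exactly as the printed model formulation.
  Two unit conventions in it are knowingly mixed in the source
  formulation: `C_i` enters in ppm while the Γ* coefficient matches
  Pa-scale literature values, and the K_c/K_o activation constants are
  printed on a kJ scale (79.43, 36.38) while Γ* uses a J scale (37830)
  with the same `R = 8.314 J mol⁻¹ K⁻¹` — making K_c and K_o nearly
  temperature-invariant as formulated. Faithfulness to the printed model
  was chosen over re-derivation; the reference values at 298.15 K are
  unaffected, and all arguments (`gas_R`, `p_o`, `eta_star`) are exposed
  should a user want a dimensionally homogeneous variant.
* The agreement index is clamped to [0, 1] against floating-point noise at
  the boundaries; it is undefined (an error) when measurements and
  estimates are all identical to the measurement mean.

## Parameters

`pft_parameters()` ships one row per vegetation type (IGBP-style codes DBF,
EBF, ENF, MF, CRO, GRA, OSH, SAV, WET, WSA): ε_msh and ε_msu means with
their across-type standard deviations kept as metadata only, the fixed VPD
ramp bounds (0.93 / 4.1 kPa for all types), per-type optimum temperature
(°C), albedo and clumping index. Deciduous needleleaf forest (DNF) carries
no parameters of its own and resolves to the DBF values. Only ε_msh and
ε_msu are ever optimized; all other parameters stay fixed.

## Calibration

`calibrate_pft()` pools all screened daily records of one vegetation type
across its sites, splits *sites* (not days) 75/25 into calibration and
validation subsets with a seeded draw, and maximizes the Willmott agreement
index

`d = 1 − Σ(Eₙ−Mₙ)² / Σ(|Eₙ−M̄| + |Mₙ−M̄|)²`

over (ε_msh, ε_msu) with a shuffled-complex-evolution (SCE-UA) optimizer.
Because GPP is linear in the two efficiencies, the model response is
precomputed once per day as two basis series (APAR of each fraction times
the scalar product), so each objective evaluation is two
multiply-adds per day. Default bounds are (0.01, 10) g C MJ⁻¹, generously
covering the shipped range 0.65–4.80. The SCE-UA configuration follows the
standard algorithm sizing for a 2-parameter problem: 2 complexes of
2n+1 = 5 points, sub-complexes of n+1 = 3, 2n+1 evolution steps per complex
per shuffle, convergence on relative best-objective improvement < 1e-6 over
5 shuffles or 10 000 evaluations; all exposed via `control`. The optimizer
is deterministic given its seed and restores the caller's RNG state.
Validation reports the pooled agreement index on held-out sites and the
mean per-site daily R².

Site-year screening follows the "less than two months" rule: a site-year
enters calibration only if every required variable (temperature, VPD, CO₂,
shortwave/PAR, observed GPP) has fewer than 60 missing days in the calendar
year; interior gaps are filled by per-variable linear interpolation in time
with no extrapolation beyond the first/last observation, and fill fractions
are reported.

## Gridded products

The product stage mirrors common archive conventions: pixel-centre
registered 0.05° lon/lat grids (rows north to south); nearest-neighbour
resampling for (categorical) land cover; an LCCS→IGBP crosswalk table
(shipped, overridable) with non-vegetated classes becoming nodata rather
than zero flux; stamped LAI series interpolated linearly in time per pixel
with endpoints held constant; 8-day aggregation on the MODIS day-of-year
grid (periods 001, 009, …, 361, the last period short); monthly and annual
calendar sums. Sub-annual products are stored as 16-bit integers with scale
factors 0.01 (8-day) and 0.1 (monthly), rounding half-away-from-zero,
nodata −32768; annual products are 64-bit floats with NaN nodata. File
names follow `<Var>_v21_<YYYY>[_<period>].tif`. Per-pixel trends are
unweighted OLS slopes of annual GPP on year with a two-sided t test;
mapped trends mask p > 0.05. An exactly linear series has zero residual
variance and is treated as maximally significant; a constant series is
masked.

Because no installed package writes signed 16-bit or 64-bit float GeoTIFF
samples, `tllue` includes a minimal uncompressed baseline-TIFF codec
(single strip per band, chained IFDs for multi-band stacks, GeoTIFF pixel
scale/tiepoint/EPSG:4326 keys, GDAL-style nodata tag). The test suite
verifies the files against an independent TIFF implementation.

## The synthetic-data generator

`make_site()` emulates a daily flux-tower record: sinusoidal seasonal
cycles for temperature, VPD and LAI (peak day configurable), lag-1
autocorrelated weather noise (coefficient 0.7, chosen to mimic synoptic
persistence), a clearness-index series that drives shortwave via the solar
geometry, a linear CO₂ ramp with a small seasonal cycle, and "observed" GPP
computed by the forward model at configured true efficiencies, perturbed by
mean-preserving multiplicative lognormal noise (flux errors scale with
magnitude) and punched with random gaps. `make_grid()` builds a small
spatially smooth driver grid with a latitudinal climate gradient, a blocky
categorical vegetation map, 8-day stamped LAI and a monthly CO₂ ramp, plus
the forward-model truth stack.

Default conditions are mid-latitude temperate (45°N, mean 283 K with 12 K
seasonal amplitude, VPD 0.9 ± 0.5 kPa, mean clearness 0.5, LAI 0.5–5
peaking at DOY 200, CO₂ 380 ppm + 2 ppm a⁻¹), three years per site.

What passing tests on synthetic data do and do not show: they demonstrate
that the estimation machinery is correct — the forward chain matches an
independent transcription, the optimizer recovers known efficiencies from
noisy self-generated data, the product pipeline conserves mass and encodes
reversibly. They do not validate the model against real ecosystems: real
flux records have correlated, non-lognormal errors, energy-balance closure
problems, LAI mismatched to tower footprints, and weather far from
sinusoidal; published per-type efficiencies can only be reproduced from the
real tower archives.

## Problem sizes in the shipped tests

The suite exercises: oracle equivalence on 1000 random admissible forcing
draws; calibration recovery on 4 synthetic sites × 3 years (noise-free and
at 20% noise, with the noisy tolerance of 15% fixed beforehand from the
spread over 15 independent Monte-Carlo repetitions); a 20 × 20-cell,
3-year grid for the product round trip; 10⁴ null pixels for the
significance-mask type-I error; and 10⁵ random series pairs for the
agreement-index bounds.

## Known limitations

* Single representative solar geometry per day; no sub-daily time stepping.
* No soil-moisture stress, no leaf energy balance, no C3/C4 crop split.
* The printed-unit CO₂ chain (see above) makes K_c/K_o effectively
  temperature-constant; the effect on C_s is small but systematic.
* The flux reader expects daily FLUXNET-style columns plus an LAI column;
  sub-daily tower files must be aggregated upstream
  (`daily_from_6hourly()` covers the 4 × 6-hourly reanalysis layout only).
* The TIFF codec reads its own output (plus any uncompressed single-strip
  baseline TIFF); it is not a general-purpose GeoTIFF reader.
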