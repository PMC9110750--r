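# tllue

Two-leaf light-use-efficiency (TL-LUE) modelling of gross primary
production (GPP), partitioned into its sunlit and shaded canopy
components, with CO₂-concentration and temperature regulation.

## Who this is for

Terrestrial carbon-cycle researchers who want to (a) estimate daily GPP,
GPP_sun and GPP_shade from flux-tower style daily forcing, (b) calibrate the
model's two maximum light-use efficiencies against eddy-covariance GPP, or
(c) run the model over gridded drivers and produce 8-day / monthly / annual
GeoTIFF products with trend analysis. A seeded synthetic-data generator with
known ground truth makes the whole chain testable without any data
downloads.

## The model

The canopy is split into sunlit leaves (absorbing direct + diffuse
radiation, prone to light saturation) and shaded leaves (diffuse only, more
efficient per unit light). Daily GPP of each fraction is

```
GPP_shade = (ε_msh × APAR_sh) × T_s × W_s × C_s
GPP_sun   = (ε_msu × APAR_su) × T_s × W_s × C_s
GPP       = GPP_shade + GPP_sun
```

where ε_msh, ε_msu are per-vegetation-type maximum light-use efficiencies
(g C MJ⁻¹), APAR_sh/APAR_su the absorbed PAR of each fraction
(MJ m⁻² d⁻¹), and the three multiplicative scalars in [0, 1] regulate for:

* **T_s** — a rational temperature response equal to 1 at the optimum
  temperature and 0 at the 273.15 / 313.15 K photosynthesis limits;
* **W_s** — a linear vapour-pressure-deficit ramp (1 below 0.93 kPa, 0 above
  4.1 kPa);
* **C_s** — CO₂ fertilization, `(C_i − Γ*) / (C_i + 2Γ*)`, with intercellular
  CO₂ `C_i = C_a·χ` from a least-cost optimality ratio χ(VPD, K) and the
  compensation point Γ* and Rubisco Michaelis–Menten coefficients following
  Arrhenius temperature responses.

Above-canopy PAR is split into direct and diffuse streams by a quartic
polynomial in the sky clearness index; sunlit/shaded leaf areas follow from
beam penetration with a clumping index; multiple scattering and under-canopy
diffuse transmission complete the absorbed-PAR terms. Calibration maximizes
the Willmott agreement index `d` between modelled and observed daily GPP
with a shuffled-complex-evolution (SCE-UA) optimizer, splitting sites 75/25
into calibration/validation sets.

See `vignettes/tllue-methods.Rmd` for the full formulation, units,
numerical decisions and limitations.

## Worked example

A mid-summer deciduous-broadleaf day (45°N, DOY 180, 20 °C, VPD 1.2 kPa,
250 W m⁻² shortwave, 400 ppm CO₂, LAI 3):

```r
library(tllue)
day <- data.frame(t_air_K = 293.15, vpd = 1.2, sw_down = 250, co2_ppm = 400,
                  lai = 3, latitude = 45, doy = 180)
gpp_step(day, "DBF")[c("gpp", "gpp_sun", "gpp_shade", "t_s", "w_s", "c_s")]
#>      gpp gpp_sun gpp_shade   t_s   w_s   c_s
#> 1 11.611   3.545     8.067 0.977 0.915 0.976
```

The canopy fixes 11.6 g C m⁻² that day, with shaded leaves contributing
about 70% — typical for a leafy canopy where diffuse light dominates
absorption. The scalars show mild temperature, water and CO₂ limitation
(each a few % below 1).

Calibrating the two efficiencies on four synthetic sites generated with the
shipped DBF truth (ε_msh = 3.75, ε_msu = 0.92) and 20% observation noise:

```r
sites <- do.call(rbind, lapply(1:4, function(i)
  make_site(synthetic_site_config(pft = "DBF", seed = 42 + i,
                                  latitude = 40 + 2 * i, noise_cv = 0.2),
            site = sprintf("SYN-%02d", i))))
calibrate_pft(sites, "DBF", seed = 1)
#> Two-leaf LUE calibration: DBF
#>   eps_msh = 3.8662  eps_msu = 0.9375  (g C MJ^-1)
#>   d (calibration) = 0.9797   d (validation) = 0.9788   R2 (validation) = 0.9195
#>   12 site-years; 3 calibration / 1 validation sites; 194 evaluations
```

Both efficiencies are recovered within a few percent of the truth despite
the noise, with high agreement on the held-out site.

For gridded work, `make_grid()` builds a toy driver stack, `run_grid()`
produces daily GPP fields, `write_product_set()` writes the 8-day, monthly
and annual GeoTIFFs (16-bit integers with scale factors 0.01 / 0.1, doubles
for annual), and `pixel_trend()` computes per-pixel OLS trends with p > 0.05
masked. A command-line wrapper covering all workflows is installed at
`system.file("cli", "tllue.R", package = "tllue")`.

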