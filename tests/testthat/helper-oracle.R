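# Independent straight-line transcription of the full model chain
# (radiation partition + regulation scalars + GPP), deliberately sharing no
# helpers with the package. Scalar-valued; used as the equivalence oracle.

oracle_day <- function(t_air_K, vpd, sw_down, co2_ppm, lai, latitude, doy,
                       eps_msh, eps_msu, t_opt_C, albedo, clumping,
                       vpd_min = 0.93, vpd_max = 4.1) {
  phi <- latitude * pi / 180
  delta <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  ws <- acos(max(-1, min(1, -tan(phi) * tan(delta))))
  if (ws <= 0) {
    return(list(gpp = 0, gpp_sun = 0, gpp_shade = 0))
  }
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws) / ws
  daylen_s <- 24 * ws / pi * 3600
  if (cosz <= 0 || lai <= 0) {
    return(list(gpp = 0, gpp_sun = 0, gpp_shade = 0))
  }

  sw_dt <- sw_down * 86400 / daylen_s
  par <- 0.43 * sw_dt
  R <- min(1, max(0, sw_dt / (1367 * cosz)))
  fd <- 0.7527 + 3.8453 * R - 16.316 * R^2 + 18.962 * R^3 - 7.0802 * R^4
  fd <- min(1, max(0, fd))
  par_dif <- par * fd
  par_dir <- par - par_dif
  lai_sun <- min(lai, 2 * cosz * (1 - exp(-lai * clumping / (2 * cosz))))
  lai_shade <- lai - lai_sun
  C <- max(0, 0.07 * clumping * par_dir * (1.1 - 0.1 * lai) * exp(-cosz))
  cosbar <- 0.537 + 0.025 * lai
  par_dif_u <- par_dif * exp(-0.5 * clumping * lai / cosbar)
  dpl <- (par_dif - par_dif_u) / lai
  apar_shade <- (1 - albedo) * (dpl + C) * lai_shade
  apar_sun <- (1 - albedo) * (par_dir * 0.5 / cosz + dpl + C) * lai_sun

  t_min <- 273.15
  t_max <- 313.15
  t_opt <- t_opt_C + 273.15
  if (t_air_K <= t_min || t_air_K >= t_max) {
    ts <- 0
  } else {
    num <- (t_air_K - t_max) * (t_air_K - t_min)
    ts <- num / (num - (t_air_K - t_opt)^2)
  }
  ws_s <- min(1, max(0, (vpd_max - vpd) / (vpd_max - vpd_min)))
  Rg <- 8.314
  g <- 4.22 * exp(37830 * (t_air_K - 298.15) / (298.15 * Rg * t_air_K))
  kc <- 39.97 * exp(79.43 * (t_air_K - 298.15) / (298.15 * Rg * t_air_K))
  ko <- 27480 * exp(36.38 * (t_air_K - 298.15) / (298.15 * Rg * t_air_K))
  K <- kc * (1 + 21 / ko)
  xi <- sqrt(356.51 * K / (1.6 * 0.8903))
  chi <- xi / (xi + sqrt(vpd))
  ci <- co2_ppm * chi
  cs <- max(0, (ci - g) / (ci + 2 * g))

  lim <- ts * ws_s * cs
  apar_sun_MJ <- apar_sun * daylen_s * 1e-6
  apar_shade_MJ <- apar_shade * daylen_s * 1e-6
  gpp_sun <- eps_msu * apar_sun_MJ * lim
  gpp_shade <- eps_msh * apar_shade_MJ * lim
  list(
    gpp = gpp_sun + gpp_shade, gpp_sun = gpp_sun, gpp_shade = gpp_shade,
    apar_sun_MJ = apar_sun_MJ, apar_shade_MJ = apar_shade_MJ,
    t_s = ts, w_s = ws_s, c_s = cs
  )
}

# Random admissible forcing + parameter draws for equivalence testing
random_admissible <- function(n, seed) {
  set.seed(seed)
  data.frame(
    t_air_K = runif(n, 274, 312),
    vpd = runif(n, 0, 5),
    sw_down = runif(n, 10, 350),
    co2_ppm = runif(n, 300, 500),
    lai = runif(n, 0.05, 8),
    latitude = runif(n, -60, 60),
    doy = sample(365, n, replace = TRUE),
    eps_msh = runif(n, 1, 5),
    eps_msu = runif(n, 0.5, 3.5),
    t_opt_C = runif(n, 18, 27),
    albedo = runif(n, 0.1, 0.25),
    clumping = runif(n, 0.5, 1)
  )
}

# Multi-site synthetic record builder shared by calibration tests
make_sites <- function(n_sites, pft = "DBF", seed_base = 100, noise_cv = 0,
                       gap_fraction = 0, years = 3) {
  do.call(rbind, lapply(seq_len(n_sites), function(i) {
    cfg <- synthetic_site_config(
      pft = pft, seed = seed_base + i, latitude = 38 + 2 * i,
      noise_cv = noise_cv, gap_fraction = gap_fraction, years = years
    )
    make_site(cfg, site = sprintf("SYN-%02d", i))
  }))
}
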