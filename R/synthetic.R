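#' Configuration for a synthetic flux site
#'
#' Defines the study conditions a generated site emulates: seasonal cycles
#' of temperature, VPD, sky clearness and LAI, a CO2 ramp, the "true"
#' maximum light-use efficiencies used to manufacture observed GPP, the
#' multiplicative observation-noise level, and the missing-data fraction.
#'
#' @param pft Vegetation-type code (parameters other than the efficiencies
#'   are taken from the shipped table).
#' @param latitude Site latitude, degrees.
#' @param years Number of calendar years.
#' @param start_year First calendar year.
#' @param true_eps_msh,true_eps_msu Ground-truth maximum light-use
#'   efficiencies, g C MJ^-1 (defaults: the shipped values for `pft`).
#' @param lai_min,lai_max,lai_peak_doy Seasonal LAI cycle: range (m^2 m^-2)
#'   and peak day of year.
#' @param t_mean_K,t_amp_K Mean and seasonal amplitude of air temperature, K.
#' @param vpd_mean,vpd_amp Mean and seasonal amplitude of VPD, kPa.
#' @param clearness_mean Mean sky clearness index.
#' @param co2_start_ppm,co2_trend_ppm CO2 at the series start and its
#'   linear trend per year, ppm.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   observation noise on GPP (0 = noise-free).
#' @param gap_fraction Fraction of days whose observations are punched out
#'   as missing.
#' @param seed Integer seed (mandatory; the series is fully reproducible).
#' @return List of class `synthetic_site_config`.
#' @export
synthetic_site_config <- function(pft = "DBF", latitude = 45, years = 3,
                                  start_year = 2001,
                                  true_eps_msh = NULL, true_eps_msu = NULL,
                                  lai_min = 0.5, lai_max = 5, lai_peak_doy = 200,
                                  t_mean_K = 283, t_amp_K = 12,
                                  vpd_mean = 0.9, vpd_amp = 0.5,
                                  clearness_mean = 0.5,
                                  co2_start_ppm = 380, co2_trend_ppm = 2,
                                  noise_cv = 0, gap_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  params <- pft_parameters(pft)
  if (is.null(true_eps_msh)) true_eps_msh <- params$eps_msh
  if (is.null(true_eps_msu)) true_eps_msu <- params$eps_msu
  stopifnot(
    lai_min >= 0, lai_max >= lai_min, noise_cv >= 0,
    gap_fraction >= 0, gap_fraction < 1, years >= 1
  )
  structure(as.list(environment())[c(
    "pft", "latitude", "years", "start_year", "true_eps_msh", "true_eps_msu",
    "lai_min", "lai_max", "lai_peak_doy", "t_mean_K", "t_amp_K",
    "vpd_mean", "vpd_amp", "clearness_mean", "co2_start_ppm",
    "co2_trend_ppm", "noise_cv", "gap_fraction", "seed"
  )], class = "synthetic_site_config")
}

.ar1_noise <- function(n, sd, rho = 0.7) {
  e <- stats::rnorm(n, 0, sd)
  x <- numeric(n)
  x[1] <- e[1]
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * e[i]
  x
}

#' Generate a synthetic flux-site record series
#'
#' Builds daily forcing from sinusoidal seasonal cycles plus lag-1
#' autocorrelated weather noise (synoptic persistence), computes "observed"
#' GPP with the forward two-leaf model at the configured true efficiencies,
#' perturbs it with multiplicative lognormal noise of the configured CV
#' (mean-preserving), and punches random gaps. Deterministic per seed.
#'
#' @param config A [synthetic_site_config()].
#' @param site Site identifier string.
#' @return Data frame of daily flux records (same layout as
#'   [read_flux_csv()]) plus a `gpp_true` column with the noise-free truth.
#' @export
make_site <- function(config, site = paste0("SYN-", config$pft)) {
  stopifnot(inherits(config, "synthetic_site_config"))
  .with_seed(config$seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
      as.Date(sprintf("%d-12-31", config$start_year + config$years - 1)),
      by = "day"
    )
    n <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    cycle <- cos(2 * pi * (doy - config$lai_peak_doy) / 365.25)

    t_air_K <- config$t_mean_K + config$t_amp_K * cycle + .ar1_noise(n, 2)
    vpd <- pmax(0, config$vpd_mean + config$vpd_amp * cycle + .ar1_noise(n, 0.3))
    clearness <- pmin(0.95, pmax(0.05, config$clearness_mean + .ar1_noise(n, 0.15)))
    lai <- config$lai_min + (config$lai_max - config$lai_min) * (cycle + 1) / 2
    frac_year <- (as.numeric(dates) - as.numeric(dates[1])) / 365.25
    co2 <- config$co2_start_ppm + config$co2_trend_ppm * frac_year +
      1.5 * cos(2 * pi * (doy - 105) / 365.25)

    cos_theta <- solar_cos_zenith(config$latitude, doy)
    daylen_s <- daylength_hours(config$latitude, doy) * 3600
    sw_daytime <- clearness * 1367 * cos_theta
    sw_down <- sw_daytime * daylen_s / 86400

    forcing <- data.frame(
      site = site, date = dates, t_air_K = t_air_K, vpd = vpd,
      sw_down = sw_down, par = 0.43 * sw_down, co2_ppm = co2, lai = lai,
      latitude = config$latitude, doy = doy
    )
    params <- pft_parameters(config$pft)
    params$eps_msh <- config$true_eps_msh
    params$eps_msu <- config$true_eps_msu
    out <- run_series(forcing, params, diagnostics = FALSE)
    gpp_true <- out$gpp

    gpp_obs <- gpp_true
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      gpp_obs <- gpp_true * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (config$gap_fraction > 0) {
      gaps <- sample(n, round(config$gap_fraction * n))
      gpp_obs[gaps] <- NA
    }
    forcing$gpp_obs <- gpp_obs
    forcing$gpp_true <- gpp_true
    forcing
  })
}

#' Generate a synthetic driver grid with known ground truth
#'
#' Builds a small lon/lat grid of spatially smooth drivers with a
#' latitudinal climate gradient, a categorical vegetation map, stamped LAI
#' slices (interpolated to daily internally by the product pipeline), a
#' monthly-resolution CO2 ramp, and the matching "truth" daily GPP stack
#' computed by the forward model — for product-pipeline round-trip tests.
#'
#' @param spec [grid_spec()] of the toy domain (default 20 x 20 cells).
#' @param years Number of years (from `start_year`).
#' @param start_year First calendar year.
#' @param pfts Vegetation-type codes scattered over the map.
#' @param seed Integer seed.
#' @return List with `drivers` (as consumed by [run_grid()], including the
#'   stamped `lai_slices`/`lai_stamps` they were interpolated from) and
#'   `truth` (output of [run_grid()] on those drivers).
#' @export
make_grid <- function(spec = grid_spec(0, 1, 44, 45, res = 0.05),
                      years = 3, start_year = 2001,
                      pfts = c("DBF", "ENF", "GRA", "CRO"), seed = 1) {
  .with_seed(seed, {
    nr <- spec$nrow
    nc <- spec$ncol
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-31", start_year + years - 1)),
      by = "day"
    )
    nd <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    lat <- matrix(grid_centers(spec)$lat, nr, nc)
    lon <- matrix(grid_centers(spec)$lon, nr, nc, byrow = TRUE)

    # blocky but spatially coherent vegetation map
    pft <- matrix(sample(pfts, nr * nc, replace = TRUE), nr, nc)
    blk <- 5
    for (i in seq(1, nr, blk)) {
      for (j in seq(1, nc, blk)) {
        ii <- i:min(nr, i + blk - 1)
        jj <- j:min(nc, j + blk - 1)
        pft[ii, jj] <- sample(pfts, 1)
      }
    }

    cycle <- cos(2 * pi * (doy - 200) / 365.25)
    smooth_field <- function(scale) {
      f <- matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
      (f + f[c(1, seq_len(nr - 1)), ] + f[, c(1, seq_len(nc - 1))]) / 3
    }
    base_t <- 284 - 0.5 * (lat - mean(lat)) + smooth_field(0.5)
    base_lai <- pmax(0.3, 3.5 + 0.15 * (lon - mean(lon)) + smooth_field(0.3))

    t_air <- array(0, c(nr, nc, nd))
    vpd <- array(0, c(nr, nc, nd))
    sw <- array(0, c(nr, nc, nd))
    t_noise <- .ar1_noise(nd, 1.5)
    r_noise <- .ar1_noise(nd, 0.1)
    v_noise <- .ar1_noise(nd, 0.2)
    for (d in seq_len(nd)) {
      t_air[, , d] <- base_t + 11 * cycle[d] + t_noise[d]
      vpd[, , d] <- pmax(0, 0.9 + 0.5 * cycle[d] + v_noise[d] + 0.001 * (lon - mean(lon)))
      R <- pmin(0.95, pmax(0.05, 0.5 + r_noise[d]))
      ct <- solar_cos_zenith(lat, doy[d])
      dls <- daylength_hours(lat, doy[d]) * 3600
      sw[, , d] <- R * 1367 * ct * dls / 86400
    }

    # stamped LAI slices every 8 days, interpolated to daily
    stamp_idx <- seq(1, nd, by = 8)
    lai_slices <- array(0, c(nr, nc, length(stamp_idx)))
    for (k in seq_along(stamp_idx)) {
      lai_slices[, , k] <- pmax(0.1, base_lai * (0.25 + 0.75 * (cycle[stamp_idx[k]] + 1) / 2))
    }
    lai_daily <- interpolate_lai_daily(lai_slices, as.numeric(dates)[stamp_idx], as.numeric(dates))

    # monthly CO2 ramp expanded to days
    ym <- format(dates, "%Y-%m")
    months <- unique(ym)
    co2_month <- 380 + 2 * (seq_along(months) - 1) / 12
    co2_daily <- co2_month[match(ym, months)]

    drivers <- list(
      spec = spec, pft = pft, lai = lai_daily, t_air_K = t_air,
      vpd = vpd, sw_down = sw, co2_ppm = co2_daily, dates = dates,
      lai_slices = lai_slices, lai_stamps = dates[stamp_idx],
      co2_monthly = data.frame(month = months, co2_ppm = co2_month)
    )
    truth <- run_grid(drivers)
    list(drivers = drivers, truth = truth)
  })
}
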