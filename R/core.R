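#' Daily two-leaf GPP for a forcing table
#'
#' Core model step. For each day: solar geometry gives the daytime-mean
#' zenith cosine and daylength; the 24-h mean shortwave flux is rescaled to a
#' daytime-mean flux, converted to PAR and split into direct and diffuse
#' streams via the clearness index; the canopy is partitioned into sunlit and
#' shaded leaf area with their absorbed PAR; absorbed fluxes are integrated
#' over daylength to MJ m^-2 d^-1; and GPP of each fraction is the product of
#' its maximum light-use efficiency, absorbed PAR, and the temperature, VPD
#' and CO2 regulation scalars. Night (polar night) or LAI = 0 gives an
#' all-zero GPP triple.
#'
#' @param forcing Data frame with columns `t_air_K` (K), `vpd` (kPa),
#'   `sw_down` (24-h mean shortwave, W m^-2), `co2_ppm`, `lai`, `latitude`
#'   (degrees) and `doy` (or `date`, from which `doy` is derived). An
#'   optional `par` column (24-h mean PAR, W m^-2) overrides the
#'   shortwave-to-PAR conversion.
#' @param params One-row parameter set from [pft_parameters()], or a
#'   vegetation-type code resolved through it.
#' @param par_factor Shortwave-to-PAR conversion factor (default 0.43).
#' @param solar_constant Solar constant, W m^-2.
#' @param diagnostics If `TRUE` (default) the returned frame carries the
#'   radiation partition and scalar columns alongside the GPP triple.
#' @return Data frame with `gpp`, `gpp_sun`, `gpp_shade` (g C m^-2 d^-1;
#'   `gpp` = `gpp_sun` + `gpp_shade` exactly) plus diagnostics.
#' @export
gpp_step <- function(forcing, params, par_factor = 0.43, solar_constant = 1367,
                     diagnostics = TRUE) {
  if (is.character(params)) params <- pft_parameters(params)
  req <- c("t_air_K", "vpd", "sw_down", "co2_ppm", "lai", "latitude")
  if (!all(req %in% names(forcing))) {
    stop("forcing must contain columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"doy" %in% names(forcing)) {
    if (!"date" %in% names(forcing)) stop("forcing needs 'doy' or 'date'", call. = FALSE)
    forcing$doy <- as.integer(format(as.Date(forcing$date), "%j"))
  }
  n <- nrow(forcing)
  cos_theta <- solar_cos_zenith(forcing$latitude, forcing$doy)
  daylen_s <- daylength_hours(forcing$latitude, forcing$doy) * 3600

  day <- cos_theta > 0 & daylen_s > 0 & forcing$lai > 0 & is.finite(forcing$sw_down)
  day[is.na(day)] <- FALSE
  sw_dt <- ifelse(day, forcing$sw_down * 86400 / daylen_s, 0)
  par_dt <- if ("par" %in% names(forcing) && any(is.finite(forcing$par))) {
    ifelse(day, forcing$par * 86400 / daylen_s, 0)
  } else {
    par_factor * sw_dt
  }

  zero <- rep(0, n)
  rad <- data.frame(
    par = zero, par_dif = zero, par_dir = zero, par_dif_u = zero,
    scatter_C = zero, lai_sun = zero, lai_shade = forcing$lai,
    apar_sun = zero, apar_shade = zero, clearness_R = zero,
    cos_theta_bar = diffuse_zenith_cosine(forcing$lai)
  )
  if (any(day)) {
    R <- clearness_index(sw_dt[day], cos_theta[day], solar_constant)
    rad[day, ] <- partition_radiation(
      par = par_dt[day], clearness_R = R, lai = forcing$lai[day],
      clumping = params$clumping, albedo = params$albedo,
      cos_theta = cos_theta[day]
    )
  }
  scal <- regulation_scalars(forcing$t_air_K, forcing$vpd, forcing$co2_ppm, params)

  apar_sun_MJ <- rad$apar_sun * daylen_s * 1e-6
  apar_shade_MJ <- rad$apar_shade * daylen_s * 1e-6
  lim <- scal$t_s * scal$w_s * scal$c_s
  gpp_sun <- params$eps_msu * apar_sun_MJ * lim
  gpp_shade <- params$eps_msh * apar_shade_MJ * lim

  out <- data.frame(
    gpp = gpp_sun + gpp_shade,
    gpp_sun = gpp_sun,
    gpp_shade = gpp_shade
  )
  if ("date" %in% names(forcing)) out <- cbind(date = forcing$date, out)
  if (diagnostics) {
    out <- cbind(
      out, rad[c(
        "par_dif", "par_dir", "par_dif_u", "scatter_C",
        "lai_sun", "lai_shade", "clearness_R"
      )],
      apar_sun_MJ = apar_sun_MJ, apar_shade_MJ = apar_shade_MJ,
      scal[c("t_s", "w_s", "c_s")],
      cos_theta = cos_theta, daylength_h = daylen_s / 3600
    )
  }
  out
}

#' Run the model over a time-ordered forcing series
#'
#' Validates temporal ordering, then applies [gpp_step()] element-wise.
#' Series totals equal the sum of daily values by construction.
#'
#' @inheritParams gpp_step
#' @return Data frame as from [gpp_step()], one row per forcing day.
#' @export
run_series <- function(forcing, params, par_factor = 0.43,
                       solar_constant = 1367, diagnostics = TRUE) {
  if (nrow(forcing) == 0) {
    return(forcing[, intersect("date", names(forcing)), drop = FALSE])
  }
  if ("date" %in% names(forcing)) {
    d <- as.Date(forcing$date)
    if (is.unsorted(d, strictly = FALSE)) {
      stop("forcing series must be sorted by date", call. = FALSE)
    }
  }
  gpp_step(forcing, params,
    par_factor = par_factor,
    solar_constant = solar_constant, diagnostics = diagnostics
  )
}
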