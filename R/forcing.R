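#' Saturated vapour pressure (Buck-type formula)
#'
#' @param t_air_C Air temperature in degrees Celsius.
#' @return Saturation vapour pressure in kPa.
#' @examples
#' saturation_vapor_pressure(0)   # 0.61121 kPa
#' saturation_vapor_pressure(20)
#' @export
saturation_vapor_pressure <- function(t_air_C) {
  if (any(!is.finite(t_air_C))) stop("t_air_C must be finite", call. = FALSE)
  0.61121 * exp((18.678 - t_air_C / 234.5) * t_air_C / (257.14 + t_air_C))
}

#' Vapour pressure deficit from specific humidity
#'
#' Computes VPD as saturation vapour pressure minus actual vapour pressure,
#' where the actual vapour pressure follows from specific humidity and
#' surface pressure. Negative values (supersaturated air) are floored at 0.
#'
#' @param spfh Specific humidity, kg kg^-1.
#' @param pres Surface pressure, Pa.
#' @param t_air_C Air temperature, degrees Celsius.
#' @return VPD in kPa (>= 0).
#' @examples
#' vapor_pressure_deficit(0.008, 101325, 20)
#' @export
vapor_pressure_deficit <- function(spfh, pres, t_air_C) {
  if (any(!is.finite(spfh)) || any(!is.finite(pres)) || any(!is.finite(t_air_C))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(pres <= 0)) stop("pres must be positive", call. = FALSE)
  vp_sat <- saturation_vapor_pressure(t_air_C)
  vp <- spfh * (pres / 1000) / (0.622 + spfh * 0.378)
  pmax(0, vp_sat - vp)
}

#' PAR from shortwave radiation
#'
#' Converts downward shortwave radiation to photosynthetically active
#' radiation with a fixed conversion factor. The default 0.43 is a site-tuned
#' value; literature estimates range roughly 0.39--0.53.
#'
#' @param sw_down Downward shortwave radiation, W m^-2 (or any energy unit;
#'   the conversion is linear).
#' @param par_factor Shortwave-to-PAR conversion factor, default 0.43.
#' @return PAR in the same units as `sw_down`.
#' @export
par_from_shortwave <- function(sw_down, par_factor = 0.43) {
  if (any(!is.finite(sw_down)) || any(sw_down < 0)) {
    stop("sw_down must be finite and >= 0", call. = FALSE)
  }
  par_factor * sw_down
}

#' Aggregate 6-hourly meteorology to daily forcing
#'
#' Collapses reanalysis-style 6-hourly records (four steps per day) to daily
#' values: shortwave energy is the sum of the four 6-hourly accumulations
#' (J m^-2 d^-1, also exposed as a 24-h mean flux in W m^-2); temperature and
#' VPD are means of the four sub-daily values, with VPD computed per step
#' from specific humidity, pressure and temperature.
#'
#' @param steps Data frame with columns `date` (Date or coercible), `dswrf`
#'   (J m^-2 per 6 h), `spfh` (kg kg^-1), `tmp` (K), `pres` (Pa).
#' @return Data frame with one row per day: `date`, `t_air_K`, `vpd` (kPa),
#'   `sw_energy` (J m^-2 d^-1), `sw_down` (W m^-2, 24-h mean).
#' @export
daily_from_6hourly <- function(steps) {
  req <- c("date", "dswrf", "spfh", "tmp", "pres")
  if (!all(req %in% names(steps))) {
    stop("steps must contain columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(steps$dswrf < 0, na.rm = TRUE)) stop("dswrf must be >= 0", call. = FALSE)
  date <- as.Date(steps$date)
  counts <- table(date)
  if (any(counts != 4)) {
    stop("each day must have exactly 4 six-hourly steps; offending day(s): ",
      paste(names(counts)[counts != 4], collapse = ", "),
      call. = FALSE
    )
  }
  vpd_step <- vapor_pressure_deficit(steps$spfh, steps$pres, steps$tmp - 273.15)
  agg <- function(x, f) as.numeric(tapply(x, date, f))
  days <- as.Date(names(counts))
  sw_energy <- agg(steps$dswrf, sum)
  data.frame(
    date = days,
    t_air_K = agg(steps$tmp, mean),
    vpd = agg(vpd_step, mean),
    sw_energy = sw_energy,
    sw_down = sw_energy / 86400
  )
}

#' Sky clearness index
#'
#' Ratio of surface shortwave irradiance to extraterrestrial irradiance on a
#' horizontal surface, R = S / (S0 cos(theta)), clipped to [0, 1] to keep the
#' diffuse-fraction polynomial inside its calibrated domain.
#'
#' @param sw_down Shortwave irradiance, W m^-2, on the same temporal basis as
#'   `cos_theta` (use a daytime-mean flux with the daytime-mean zenith cosine).
#' @param cos_theta Cosine of the solar zenith angle (> 0; night is undefined).
#' @param solar_constant Solar constant, W m^-2 (default 1367).
#' @return Clearness index in [0, 1].
#' @export
clearness_index <- function(sw_down, cos_theta, solar_constant = 1367) {
  if (any(!is.finite(sw_down)) || any(sw_down < 0)) {
    stop("sw_down must be finite and >= 0", call. = FALSE)
  }
  if (any(cos_theta <= 0)) {
    stop("clearness index undefined for cos_theta <= 0 (night)", call. = FALSE)
  }
  pmin(1, pmax(0, sw_down / (solar_constant * cos_theta)))
}

#' Screen site-years and gap-fill flux records
#'
#' A site-year is accepted only if, for each required variable, the number of
#' missing days is below `max_missing_days` (the "less than two months" rule).
#' Within accepted years, interior gaps are filled by linear interpolation in
#' time per variable; no extrapolation beyond the first/last observed value.
#' Quality flags per required variable record whether each day was observed,
#' interpolated, or is still missing.
#'
#' @param records Data frame of daily flux records with columns `site`,
#'   `date`, and the required variables.
#' @param max_missing_days Threshold (default 60): accept when missing days
#'   are strictly fewer than this.
#' @param vars Required variables screened and gap-filled.
#' @return List with `summary` (one row per site-year: missing-day counts per
#'   variable, `accepted`, `fill_fraction`) and `records` (gap-filled records
#'   of accepted site-years with `<var>_qc` flag columns).
#' @export
screen_site_years <- function(records,
                              max_missing_days = 60,
                              vars = c("t_air_K", "vpd", "sw_down", "co2_ppm", "gpp_obs")) {
  if (nrow(records) == 0) {
    return(list(summary = data.frame(), records = records))
  }
  if (!all(c("site", "date") %in% names(records))) {
    stop("records must contain 'site' and 'date' columns", call. = FALSE)
  }
  miss <- !all(vars %in% names(records))
  if (miss) stop("records lack required variables", call. = FALSE)
  records$date <- as.Date(records$date)
  year <- as.integer(format(records$date, "%Y"))
  key <- interaction(records$site, year, drop = TRUE)

  out_summary <- list()
  out_records <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    chunk <- records[idx, , drop = FALSE]
    chunk <- chunk[order(chunk$date), , drop = FALSE]
    n_missing <- vapply(vars, function(v) sum(!is.finite(chunk[[v]])), integer(1))
    accepted <- all(n_missing < max_missing_days)
    n_filled <- 0L
    if (accepted) {
      t_num <- as.numeric(chunk$date)
      for (v in vars) {
        x <- chunk[[v]]
        qc <- ifelse(is.finite(x), "observed", "missing")
        bad <- !is.finite(x)
        if (any(bad) && sum(!bad) >= 2) {
          filled <- stats::approx(t_num[!bad], x[!bad], xout = t_num, rule = 1)$y
          fill_ok <- bad & is.finite(filled)
          x[fill_ok] <- filled[fill_ok]
          qc[fill_ok] <- "interpolated"
          n_filled <- n_filled + sum(fill_ok)
        }
        chunk[[v]] <- x
        chunk[[paste0(v, "_qc")]] <- qc
      }
      out_records[[k]] <- chunk
    }
    out_summary[[k]] <- data.frame(
      site = chunk$site[1], year = as.integer(format(chunk$date[1], "%Y")),
      n_days = nrow(chunk),
      t(n_missing),
      accepted = accepted,
      fill_fraction = if (accepted) n_filled / (nrow(chunk) * length(vars)) else NA_real_
    )
  }
  summary <- do.call(rbind, out_summary)
  rownames(summary) <- NULL
  recs <- if (length(out_records)) do.call(rbind, out_records) else records[0, , drop = FALSE]
  rownames(recs) <- NULL
  list(summary = summary, records = recs)
}

#' Read a FLUXNET-style daily flux CSV
#'
#' Reads a delimited daily file whose header uses FLUXNET2015 FULLSET field
#' names: `TIMESTAMP` (YYYYMMDD), `TA_F` (deg C), `VPD_F` (hPa), `CO2_F_MDS`
#' (ppm), `PPFD_IN` (umol m^-2 s^-1), `SW_IN_F` (W m^-2),
#' `GPP_DT_CUT_MEAN` (g C m^-2 d^-1), plus `LAI` (m^2 m^-2). The value -9999
#' is the missing sentinel. VPD is converted from hPa to kPa; PAR is taken
#' from `PPFD_IN` (1 W m^-2 of PAR ~ 4.57 umol m^-2 s^-1) when present,
#' otherwise from shortwave via `par_factor`.
#'
#' @param path Path to the CSV file.
#' @param site Site identifier; defaults to the file name without extension.
#' @param latitude Site latitude in degrees (required for solar geometry).
#' @param par_factor Shortwave-to-PAR factor used when `PPFD_IN` is absent.
#' @return Data frame of daily flux records (`site`, `date`, `t_air_K`,
#'   `vpd`, `sw_down`, `par`, `co2_ppm`, `lai`, `gpp_obs`, `latitude`,
#'   `doy`).
#' @export
read_flux_csv <- function(path, site = NULL, latitude = NA_real_, par_factor = 0.43) {
  raw <- utils::read.csv(path, check.names = FALSE)
  raw[raw == -9999] <- NA
  if (is.null(site)) site <- sub("\\.[^.]*$", "", basename(path))
  if (!"TIMESTAMP" %in% names(raw)) stop("missing TIMESTAMP column", call. = FALSE)
  date <- as.Date(as.character(raw$TIMESTAMP), format = "%Y%m%d")
  get <- function(nm) if (nm %in% names(raw)) as.numeric(raw[[nm]]) else rep(NA_real_, nrow(raw))
  if ("LATITUDE" %in% names(raw) && is.na(latitude)) latitude <- raw$LATITUDE[1]
  sw <- get("SW_IN_F")
  ppfd <- get("PPFD_IN")
  par <- ifelse(is.finite(ppfd), ppfd / 4.57, ifelse(is.finite(sw), par_factor * sw, NA_real_))
  data.frame(
    site = site,
    date = date,
    t_air_K = get("TA_F") + 273.15,
    vpd = get("VPD_F") / 10,
    sw_down = sw,
    par = par,
    co2_ppm = get("CO2_F_MDS"),
    lai = get("LAI"),
    gpp_obs = get("GPP_DT_CUT_MEAN"),
    latitude = latitude,
    doy = as.integer(format(date, "%j"))
  )
}

#' Write a FLUXNET-style daily flux CSV
#'
#' Inverse of [read_flux_csv()]: writes daily records under FLUXNET2015
#' FULLSET column names with -9999 as missing sentinel (VPD back in hPa).
#'
#' @param records Data frame as returned by [read_flux_csv()] or
#'   [make_site()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_flux_csv <- function(records, path) {
  out <- data.frame(
    TIMESTAMP = format(as.Date(records$date), "%Y%m%d"),
    TA_F = records$t_air_K - 273.15,
    VPD_F = records$vpd * 10,
    SW_IN_F = records$sw_down,
    CO2_F_MDS = records$co2_ppm,
    LAI = records$lai,
    GPP_DT_CUT_MEAN = records$gpp_obs,
    LATITUDE = records$latitude
  )
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.finite(x), x, -9999))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
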