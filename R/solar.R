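#' Solar declination angle
#'
#' Cooper's approximation of the solar declination for a given day of year.
#'
#' @param doy Day of year (1--366).
#' @return Declination in radians.
#' @keywords internal
solar_declination <- function(doy) {
  23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
}

.check_lat_doy <- function(latitude, doy) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("latitude must be finite and within [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(doy)) || any(doy < 1) || any(doy > 366)) {
    stop("doy must be within [1, 366]", call. = FALSE)
  }
}

#' Sunset hour angle
#'
#' @param latitude Latitude in decimal degrees.
#' @param doy Day of year.
#' @return Hour angle at sunset in radians; 0 during polar night, pi during
#'   polar day.
#' @keywords internal
sunset_hour_angle <- function(latitude, doy) {
  phi <- latitude * pi / 180
  delta <- solar_declination(doy)
  x <- -tan(phi) * tan(delta)
  acos(pmin(1, pmax(-1, x)))
}

#' Daytime-mean cosine of the solar zenith angle
#'
#' Mean of cos(theta) over the sunlit hour-angle range for one day, from
#' standard solar-declination geometry. The model runs at a daily step, so a
#' single representative zenith cosine per day is used for beam penetration
#' and the clearness index.
#'
#' @param latitude Latitude in decimal degrees (-90 to 90).
#' @param doy Day of year (1 to 366).
#' @return Daytime-mean cos(theta), dimensionless; 0 during polar night.
#' @examples
#' solar_cos_zenith(45, 172)
#' solar_cos_zenith(80, 355) # polar night -> 0
#' @export
solar_cos_zenith <- function(latitude, doy) {
  .check_lat_doy(latitude, doy)
  phi <- latitude * pi / 180
  delta <- solar_declination(doy)
  ws <- sunset_hour_angle(latitude, doy)
  out <- ifelse(ws > 0,
    sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws) / pmax(ws, .Machine$double.eps),
    0
  )
  pmax(0, out)
}

#' Daylength
#'
#' @param latitude Latitude in decimal degrees.
#' @param doy Day of year.
#' @return Daylength in hours (0 during polar night, 24 during polar day).
#' @export
daylength_hours <- function(latitude, doy) {
  .check_lat_doy(latitude, doy)
  24 * sunset_hour_angle(latitude, doy) / pi
}
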