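#' Temperature regulation scalar
#'
#' TEM-style rational temperature response: 1 at the optimum temperature,
#' 0 at or beyond the photosynthesis temperature limits.
#'
#' @param t_air_K Air temperature, K.
#' @param t_opt_K Optimum temperature for photosynthesis, K (per vegetation
#'   type).
#' @param t_min_K,t_max_K Minimum and maximum temperature for photosynthesis,
#'   K (defaults 273.15 and 313.15).
#' @return Scalar in [0, 1].
#' @export
temperature_scalar <- function(t_air_K, t_opt_K,
                               t_min_K = 273.15, t_max_K = 313.15) {
  if (any(!(t_min_K < t_opt_K & t_opt_K < t_max_K))) {
    stop("require t_min < t_opt < t_max", call. = FALSE)
  }
  num <- (t_air_K - t_max_K) * (t_air_K - t_min_K)
  den <- num - (t_air_K - t_opt_K)^2
  ts <- ifelse(t_air_K <= t_min_K | t_air_K >= t_max_K, 0, num / den)
  pmin(1, pmax(0, ts))
}

#' Water (VPD) regulation scalar
#'
#' Linear ramp in vapour pressure deficit: 1 at or below `vpd_min`, 0 at or
#' above `vpd_max`.
#'
#' @param vpd Vapour pressure deficit, kPa.
#' @param vpd_min,vpd_max VPD at which GPP is unconstrained / fully
#'   suppressed, kPa (defaults 0.93 and 4.1).
#' @return Scalar in [0, 1].
#' @export
water_scalar <- function(vpd, vpd_min = 0.93, vpd_max = 4.1) {
  if (any(vpd_min >= vpd_max)) stop("require vpd_min < vpd_max", call. = FALSE)
  ws <- (vpd_max - vpd) / (vpd_max - vpd_min)
  pmin(1, pmax(0, ws))
}

#' CO2 compensation point without dark respiration
#'
#' Arrhenius temperature response of Gamma-star with activation energy
#' 37830 J mol^-1; equals 4.22 (model units) at 298.15 K.
#'
#' @param t_air_K Air temperature, K (> 0).
#' @param gas_R Molar gas constant, J mol^-1 K^-1 (default 8.314).
#' @return Gamma-star in model units (as printed; see the methods vignette
#'   for the ppm-vs-Pa unit caveat).
#' @export
gamma_star <- function(t_air_K, gas_R = 8.314) {
  if (any(t_air_K <= 0)) stop("t_air_K must be > 0", call. = FALSE)
  4.22 * exp(37830 * (t_air_K - 298.15) / (298.15 * gas_R * t_air_K))
}

#' Michaelis-Menten coefficients of Rubisco
#'
#' Temperature responses of the Rubisco coefficients for CO2 (`k_c`, 39.97 at
#' 298.15 K) and O2 (`k_o`, 27480 at 298.15 K), combined into
#' K = k_c (1 + P_o / k_o) with O2 partial pressure P_o = 21 kPa. The
#' activation constants are used exactly as printed in the source model
#' formulation (79.43 and 36.38 with R in J mol^-1 K^-1), which makes k_c and
#' k_o nearly temperature-invariant; see the methods vignette.
#'
#' @param t_air_K Air temperature, K (> 0).
#' @param gas_R Molar gas constant, J mol^-1 K^-1.
#' @param p_o O2 partial pressure, kPa (default 21).
#' @return List with `k_c`, `k_o`, `K`.
#' @export
michaelis_coefficients <- function(t_air_K, gas_R = 8.314, p_o = 21) {
  if (any(t_air_K <= 0)) stop("t_air_K must be > 0", call. = FALSE)
  k_c <- 39.97 * exp(79.43 * (t_air_K - 298.15) / (298.15 * gas_R * t_air_K))
  k_o <- 27480 * exp(36.38 * (t_air_K - 298.15) / (298.15 * gas_R * t_air_K))
  list(k_c = k_c, k_o = k_o, K = k_c * (1 + p_o / k_o))
}

#' Ratio of leaf-internal to ambient CO2
#'
#' Least-cost optimality form: chi = xi / (xi + sqrt(VPD)) with
#' xi = sqrt(356.51 K / (1.6 eta-star)), where eta-star is the viscosity of
#' water relative to 25 degrees C.
#'
#' @param vpd Vapour pressure deficit, kPa (>= 0).
#' @param K Combined Michaelis-Menten coefficient from
#'   [michaelis_coefficients()].
#' @param eta_star Relative water viscosity (default 0.8903).
#' @return List with `chi` in (0, 1] and `xi`.
#' @export
chi_ratio <- function(vpd, K, eta_star = 0.8903) {
  if (any(vpd < 0)) stop("vpd must be >= 0", call. = FALSE)
  xi <- sqrt(356.51 * K / (1.6 * eta_star))
  list(chi = xi / (xi + sqrt(vpd)), xi = xi)
}

#' CO2 regulation scalar
#'
#' Full CO2-fertilization chain: intercellular CO2 C_i = C_a * chi, then
#' C_s = (C_i - Gamma-star) / (C_i + 2 Gamma-star), floored at 0 when
#' C_i <= Gamma-star. Always strictly below 1 and increasing in C_a.
#'
#' @param co2_ppm Ambient CO2 mole fraction C_a, ppm (> 0).
#' @param vpd Vapour pressure deficit, kPa.
#' @param t_air_K Air temperature, K.
#' @param gas_R Molar gas constant, J mol^-1 K^-1.
#' @param eta_star Relative water viscosity.
#' @param p_o O2 partial pressure, kPa.
#' @return List with `c_s` and `intermediates` (data frame: `gamma_star`,
#'   `c_i`, `chi`, `xi`, `K`, `k_c`, `k_o`).
#' @export
co2_scalar <- function(co2_ppm, vpd, t_air_K, gas_R = 8.314,
                       eta_star = 0.8903, p_o = 21) {
  if (any(co2_ppm <= 0)) stop("co2_ppm must be > 0", call. = FALSE)
  gs <- gamma_star(t_air_K, gas_R)
  mm <- michaelis_coefficients(t_air_K, gas_R, p_o)
  ch <- chi_ratio(vpd, mm$K, eta_star)
  c_i <- co2_ppm * ch$chi
  c_s <- pmax(0, (c_i - gs) / (c_i + 2 * gs))
  list(
    c_s = c_s,
    intermediates = data.frame(
      gamma_star = gs, c_i = c_i, chi = ch$chi, xi = ch$xi,
      K = mm$K, k_c = mm$k_c, k_o = mm$k_o
    )
  )
}

#' All three regulation scalars for a forcing series
#'
#' @param t_air_K Air temperature, K.
#' @param vpd Vapour pressure deficit, kPa.
#' @param co2_ppm Ambient CO2, ppm.
#' @param params One-row vegetation parameter set from [pft_parameters()]
#'   (uses `t_opt_C`, `vpd_min`, `vpd_max`).
#' @return Data frame with `t_s`, `w_s`, `c_s` and the CO2 intermediates.
#' @export
regulation_scalars <- function(t_air_K, vpd, co2_ppm, params) {
  cs <- co2_scalar(co2_ppm, vpd, t_air_K)
  out <- data.frame(
    t_s = temperature_scalar(t_air_K, params$t_opt_C + 273.15),
    w_s = water_scalar(vpd, params$vpd_min, params$vpd_max),
    c_s = cs$c_s
  )
  cbind(out, cs$intermediates)
}
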