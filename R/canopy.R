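#' Diffuse fraction of PAR from the sky clearness index
#'
#' Quartic polynomial in the clearness index R giving the fraction of
#' above-canopy PAR that is diffuse; clipped to [0, 1].
#'
#' @param clearness_R Clearness index in [0, 1].
#' @return Diffuse fraction in [0, 1].
#' @examples
#' diffuse_fraction(0) # overcast sky: 0.7527
#' @export
diffuse_fraction <- function(clearness_R) {
  if (any(!is.finite(clearness_R)) || any(clearness_R < 0) || any(clearness_R > 1)) {
    stop("clearness_R must be within [0, 1]", call. = FALSE)
  }
  R <- clearness_R
  f <- 0.7527 + 3.8453 * R - 16.316 * R^2 + 18.962 * R^3 - 7.0802 * R^4
  pmin(1, pmax(0, f))
}

#' Split PAR into diffuse and direct streams
#'
#' @param par Above-canopy PAR, W m^-2 (>= 0).
#' @param clearness_R Clearness index in [0, 1].
#' @return List with `par_dif` and `par_dir` (W m^-2); they sum exactly to
#'   `par`.
#' @export
split_par <- function(par, clearness_R) {
  if (any(!is.finite(par)) || any(par < 0)) stop("par must be >= 0", call. = FALSE)
  par_dif <- par * diffuse_fraction(clearness_R)
  list(par_dif = par_dif, par_dir = par - par_dif)
}

#' Sunlit and shaded leaf area index
#'
#' Beam-penetration split of canopy LAI: the sunlit fraction saturates at
#' 2 cos(theta) for dense canopies. The sunlit LAI is capped at the total LAI
#' (the exponential form can marginally exceed it for sparse canopies at high
#' sun) so the shaded LAI is never negative.
#'
#' @param lai Leaf area index, m^2 m^-2.
#' @param clumping Clumping index Omega in (0, 1].
#' @param cos_theta Cosine of the solar zenith angle (> 0).
#' @return List with `lai_sun` and `lai_shade`; they sum exactly to `lai`.
#' @export
sunlit_shaded_lai <- function(lai, clumping, cos_theta) {
  if (any(cos_theta <= 0)) stop("cos_theta must be > 0 (daylight)", call. = FALSE)
  if (any(lai < 0)) stop("lai must be >= 0", call. = FALSE)
  lai_sun <- 2 * cos_theta * (1 - exp(-lai * clumping / (2 * cos_theta)))
  lai_sun <- pmin(lai, lai_sun)
  list(lai_sun = lai_sun, lai_shade = lai - lai_sun)
}

#' Multiple-scattered radiation
#'
#' Empirical multiple-scattering term C added to the per-leaf diffuse flux.
#' The linear LAI term (1.1 - 0.1 LAI) goes negative above LAI = 11, where C
#' is floored at 0.
#'
#' @param par_dir Direct-beam PAR, W m^-2.
#' @param lai Leaf area index.
#' @param clumping Clumping index Omega.
#' @param cos_theta Cosine of the solar zenith angle.
#' @return Scattered radiation C, W m^-2 (>= 0).
#' @export
multiple_scatter <- function(par_dir, lai, clumping, cos_theta) {
  if (any(par_dir < 0)) stop("par_dir must be >= 0", call. = FALSE)
  pmax(0, 0.07 * clumping * par_dir * (1.1 - 0.1 * lai) * exp(-cos_theta))
}

#' Representative zenith cosine for diffuse transmission
#'
#' @param lai Leaf area index.
#' @return cos(theta-bar) = 0.537 + 0.025 LAI.
#' @export
diffuse_zenith_cosine <- function(lai) {
  0.537 + 0.025 * lai
}

#' Diffuse PAR under the canopy
#'
#' Beer-law transmission of diffuse PAR through the canopy at the
#' representative diffuse zenith angle.
#'
#' @param par_dif Above-canopy diffuse PAR, W m^-2.
#' @param lai Leaf area index.
#' @param clumping Clumping index Omega.
#' @return Under-canopy diffuse PAR, W m^-2 (<= `par_dif`).
#' @export
under_canopy_diffuse <- function(par_dif, lai, clumping) {
  if (any(par_dif < 0)) stop("par_dif must be >= 0", call. = FALSE)
  par_dif * exp(-0.5 * clumping * lai / diffuse_zenith_cosine(lai))
}

#' Partition above-canopy PAR into sunlit and shaded absorbed PAR
#'
#' Full canopy radiation decomposition: diffuse/direct split from the
#' clearness index, sunlit/shaded LAI from beam penetration, multiple
#' scattering, under-canopy diffuse transmission, and absorbed PAR per
#' canopy fraction. Shaded leaves absorb the diffuse flux gradient plus
#' scattering; sunlit leaves additionally absorb the direct beam projected
#' with leaf angle beta (default 60 degrees, cos(beta) = 0.5). At LAI = 0
#' both absorbed fluxes are 0 (no canopy).
#'
#' All fluxes are instantaneous W m^-2 on the temporal basis of `par`.
#'
#' @param par Above-canopy PAR, W m^-2.
#' @param clearness_R Sky clearness index in [0, 1].
#' @param lai Leaf area index, m^2 m^-2.
#' @param clumping Clumping index Omega in (0, 1].
#' @param albedo Canopy albedo alpha in [0, 1).
#' @param cos_theta Cosine of the solar zenith angle (> 0).
#' @param leaf_angle_deg Leaf angle beta in degrees (default 60).
#' @return Data frame with columns `par`, `par_dif`, `par_dir`, `par_dif_u`,
#'   `scatter_C`, `lai_sun`, `lai_shade`, `apar_sun`, `apar_shade`,
#'   `clearness_R`, `cos_theta_bar`.
#' @export
partition_radiation <- function(par, clearness_R, lai, clumping, albedo,
                                cos_theta, leaf_angle_deg = 60) {
  sp <- split_par(par, clearness_R)
  ll <- sunlit_shaded_lai(lai, clumping, cos_theta)
  C <- multiple_scatter(sp$par_dir, lai, clumping, cos_theta)
  par_dif_u <- under_canopy_diffuse(sp$par_dif, lai, clumping)
  cos_beta <- cos(leaf_angle_deg * pi / 180)
  dif_per_lai <- ifelse(lai > 0, (sp$par_dif - par_dif_u) / lai, 0)
  apar_shade <- ifelse(lai > 0, (1 - albedo) * (dif_per_lai + C) * ll$lai_shade, 0)
  apar_sun <- ifelse(lai > 0,
    (1 - albedo) * (sp$par_dir * cos_beta / cos_theta + dif_per_lai + C) * ll$lai_sun,
    0
  )
  data.frame(
    par = par,
    par_dif = sp$par_dif,
    par_dir = sp$par_dir,
    par_dif_u = par_dif_u,
    scatter_C = C,
    lai_sun = ll$lai_sun,
    lai_shade = ll$lai_shade,
    apar_sun = pmax(0, apar_sun),
    apar_shade = pmax(0, apar_shade),
    clearness_R = clearness_R,
    cos_theta_bar = diffuse_zenith_cosine(lai)
  )
}
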