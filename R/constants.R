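#' Dual-beam Doppler OCT device and physiology constants
#'
#' Bundles the constants entering the bidirectional Doppler velocity
#' equation: the source centre wavelength \eqn{\lambda}, the time interval
#' \eqn{\tau} between the two phase recordings, the group refractive index
#' of blood \eqn{n}, the angular separation \eqn{\Delta\alpha} of the two
#' probe beams, and the angle \eqn{\beta} between the detection plane
#' spanned by the beams and the velocity vector.
#'
#' The defaults describe a plausible 840 nm dual-beam system and are meant
#' to be overridden with the constants of the actual instrument; none of
#' them is a universal physical constant.
#'
#' @param wavelength_m Source centre wavelength in metres.
#' @param tau_s Time interval between the two recordings in seconds.
#' @param n_blood Group refractive index of blood (dimensionless, >= 1).
#' @param dalpha_rad Angular separation of the probe beams in radians.
#' @param beta_deg Angle between detection plane and velocity vector in
#'   degrees. May be overridden per vessel in [total_retinal_blood_flow()].
#' @param cos_beta_floor Minimum tolerated \eqn{|\cos\beta|}; below it the
#'   velocity equation is ill-conditioned and an error is raised.
#' @return An object of class `doct_constants`.
#' @seealso [doppler_velocity()], [total_retinal_blood_flow()]
#' @export
#' @examples
#' doct_constants(wavelength_m = 8.4e-7, tau_s = 2.5e-5, beta_deg = 65)
doct_constants <- function(wavelength_m = 8.4e-7,
                           tau_s = 2.5e-5,
                           n_blood = 1.38,
                           dalpha_rad = 0.0095,
                           beta_deg = 65,
                           cos_beta_floor = 0.05) {
  stopifnot(
    is.numeric(wavelength_m), length(wavelength_m) == 1L, wavelength_m > 0,
    is.numeric(tau_s), length(tau_s) == 1L, tau_s > 0,
    is.numeric(n_blood), length(n_blood) == 1L, n_blood >= 1,
    is.numeric(dalpha_rad), length(dalpha_rad) == 1L, dalpha_rad > 0,
    is.numeric(beta_deg), length(beta_deg) == 1L,
    is.numeric(cos_beta_floor), length(cos_beta_floor) == 1L,
    cos_beta_floor > 0
  )
  obj <- list(
    wavelength_m = wavelength_m, tau_s = tau_s, n_blood = n_blood,
    dalpha_rad = dalpha_rad, beta_deg = beta_deg,
    cos_beta_floor = cos_beta_floor
  )
  class(obj) <- "doct_constants"
  if (abs(cos(beta_deg * pi / 180)) <= cos_beta_floor) {
    stop("doct_constants: |cos(beta)| at or below floor (", cos_beta_floor,
         "); velocity is ill-conditioned near beta = 90 degrees",
         call. = FALSE)
  }
  obj
}

#' @export
print.doct_constants <- function(x, ...) {
  cat("Dual-beam DOCT constants\n")
  cat(sprintf("  wavelength  %.1f nm\n", x$wavelength_m * 1e9))
  cat(sprintf("  tau         %.2f us\n", x$tau_s * 1e6))
  cat(sprintf("  n (blood)   %.3f\n", x$n_blood))
  cat(sprintf("  delta-alpha %.2f mrad\n", x$dalpha_rad * 1e3))
  cat(sprintf("  beta        %.1f deg\n", x$beta_deg))
  invisible(x)
}

#' Oxygen content model parameters
#'
#' Physiological constants of the blood oxygen-content model: haemoglobin
#' concentration, the Huefner number (oxygen-binding capacity per gram of
#' haemoglobin), the plasma solubility coefficient for dissolved oxygen,
#' and the Hill dissociation-curve parameters used to recover a partial
#' pressure from a saturation. `sat_distance_coeff` is the slope of the
#' linear correction applied to a vessel's measured saturation per mm of
#' distance between its measurement point and the central-vessel trunk;
#' the default 0 disables the correction.
#'
#' @param hb_g_dl Haemoglobin concentration, g/dL.
#' @param huefner_ml_g Huefner number, mL O2 per g haemoglobin.
#' @param solubility_ml_dl_mmhg Plasma O2 solubility, mL O2 per dL per mmHg.
#' @param hill_p50_mmhg Half-saturation oxygen tension of the Hill curve,
#'   mmHg.
#' @param hill_n Hill exponent (dimensionless).
#' @param po2_cap_mmhg Cap on the inferred partial pressure, mmHg. The Hill
#'   inverse diverges as saturation approaches 1; the cap keeps the small
#'   dissolved fraction bounded.
#' @param sat_distance_coeff Saturation correction slope, fraction per mm.
#'   Positive values raise arterial saturations measured downstream of the
#'   trunk back toward their central value.
#' @return An object of class `oxygen_model_params`.
#' @seealso [oxygen_content()], [correct_saturation()]
#' @export
oxygen_model_params <- function(hb_g_dl = 15.0,
                                huefner_ml_g = 1.34,
                                solubility_ml_dl_mmhg = 0.0031,
                                hill_p50_mmhg = 26.6,
                                hill_n = 2.7,
                                po2_cap_mmhg = 100,
                                sat_distance_coeff = 0) {
  stopifnot(
    hb_g_dl > 0, huefner_ml_g > 0, solubility_ml_dl_mmhg > 0,
    hill_p50_mmhg > 0, hill_n > 0, po2_cap_mmhg > 0,
    is.numeric(sat_distance_coeff), length(sat_distance_coeff) == 1L
  )
  obj <- list(
    hb_g_dl = hb_g_dl, huefner_ml_g = huefner_ml_g,
    solubility_ml_dl_mmhg = solubility_ml_dl_mmhg,
    hill_p50_mmhg = hill_p50_mmhg, hill_n = hill_n,
    po2_cap_mmhg = po2_cap_mmhg,
    sat_distance_coeff = sat_distance_coeff
  )
  class(obj) <- "oxygen_model_params"
  obj
}

#' @export
print.oxygen_model_params <- function(x, ...) {
  cat("Oxygen content model parameters\n")
  cat(sprintf("  Hb %.1f g/dL, Huefner %.2f mL/g, solubility %.4f mL/dL/mmHg\n",
              x$hb_g_dl, x$huefner_ml_g, x$solubility_ml_dl_mmhg))
  cat(sprintf("  Hill p50 %.1f mmHg, n %.2f, pO2 cap %.0f mmHg\n",
              x$hill_p50_mmhg, x$hill_n, x$po2_cap_mmhg))
  cat(sprintf("  distance correction %.4f /mm\n", x$sat_distance_coeff))
  invisible(x)
}

# internal: clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
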