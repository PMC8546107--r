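#' Distance-correct a measured vessel oxygen saturation
#'
#' Applies a linear correction for the distance between a vessel's
#' saturation measurement point and the central-vessel trunk (the merging
#' point of the central retinal artery or vein), then clamps the result to
#' the physical range \eqn{[0, 1]}. With the default coefficient of 0 the
#' correction is the identity; the stage exists so that an instrument- or
#' study-specific slope can be plugged in.
#'
#' @param s_measured Measured saturation, fraction in \eqn{[0, 1]}
#'   (vectorised).
#' @param distance_mm Distance of the measurement point to the trunk, mm.
#' @param coeff Correction slope, saturation fraction per mm.
#' @return Corrected saturation fraction, clamped to \eqn{[0, 1]}.
#' @export
correct_saturation <- function(s_measured, distance_mm, coeff = 0) {
  stopifnot(is.numeric(s_measured), is.numeric(distance_mm),
            is.numeric(coeff))
  if (any(s_measured < 0 | s_measured > 1)) {
    stop("correct_saturation: measured saturation outside [0, 1]",
         call. = FALSE)
  }
  if (any(distance_mm < 0)) {
    stop("correct_saturation: negative distance", call. = FALSE)
  }
  clamp(s_measured + coeff * distance_mm, 0, 1)
}

#' Central retinal artery saturation
#'
#' The saturation in the central retinal artery is the unweighted mean of
#' the distance-corrected saturations of the branching arteries: arterial
#' blood is distributed from, not mixed into, the trunk, so no flow
#' weighting applies.
#'
#' @param corrected_sats Numeric vector of corrected arterial saturations.
#' @return Saturation fraction.
#' @export
central_artery_saturation <- function(corrected_sats) {
  if (length(corrected_sats) == 0L || !is.numeric(corrected_sats)) {
    stop("central_artery_saturation: need at least one arterial saturation",
         call. = FALSE)
  }
  mean(corrected_sats)
}

#' Central retinal vein saturation (flow-weighted)
#'
#' Venous blood in the central retinal vein is the mixture of all merging
#' retinal veins, so the central saturation is the flow-weighted mean of
#' the corrected per-vein saturations:
#' \eqn{S_{CRV} = \sum_i Q_i S_i / \sum_i Q_i}.
#'
#' @param corrected_sats Corrected venous saturation fractions.
#' @param flows_ul_min Per-vein volumetric flows used as weights
#'   (\eqn{\mu}l/min); must contain at least one positive flow.
#' @return Saturation fraction, bounded by the input range.
#' @export
central_vein_saturation <- function(corrected_sats, flows_ul_min) {
  if (length(corrected_sats) == 0L) {
    stop("central_vein_saturation: need at least one vein", call. = FALSE)
  }
  stopifnot(length(corrected_sats) == length(flows_ul_min),
            is.numeric(flows_ul_min))
  if (any(flows_ul_min < 0)) {
    stop("central_vein_saturation: negative flow weight", call. = FALSE)
  }
  if (sum(flows_ul_min) <= 0) {
    stop("central_vein_saturation: all flow weights are zero", call. = FALSE)
  }
  sum(flows_ul_min * corrected_sats) / sum(flows_ul_min)
}

#' Oxygen content of blood at a given saturation
#'
#' Total oxygen content is haemoglobin-bound plus plasma-dissolved oxygen.
#' The bound part is `hb_g_dl * huefner_ml_g * sat` (mL O2 per dL). The
#' dissolved part needs an oxygen tension, recovered from the saturation by
#' inverting the Hill dissociation curve,
#' \eqn{pO_2 = p_{50} (s / (1 - s))^{1/n}}, capped at `po2_cap_mmhg`
#' (the inverse diverges as \eqn{s \to 1}) and set to 0 at \eqn{s = 0};
#' dissolved content is then `solubility * pO2`. The sum is converted from
#' mL/dL to mL O2 per mL blood.
#'
#' @param sat Saturation fraction in \eqn{[0, 1]} (vectorised).
#' @param params An [oxygen_model_params()] object.
#' @return Oxygen content in mL O2 per mL blood; strictly increasing in
#'   `sat`.
#' @export
#' @examples
#' oxygen_content(0.95, oxygen_model_params())  # ~0.193 mL O2 / mL
oxygen_content <- function(sat, params = oxygen_model_params()) {
  stopifnot(inherits(params, "oxygen_model_params"), is.numeric(sat))
  if (any(sat < 0 | sat > 1)) {
    stop("oxygen_content: saturation outside [0, 1]", call. = FALSE)
  }
  bound_ml_dl <- params$hb_g_dl * params$huefner_ml_g * sat
  po2 <- ifelse(
    sat <= 0, 0,
    ifelse(sat >= 1, params$po2_cap_mmhg,
           pmin(params$po2_cap_mmhg,
                params$hill_p50_mmhg * (sat / (1 - sat))^(1 / params$hill_n)))
  )
  dissolved_ml_dl <- params$solubility_ml_dl_mmhg * po2
  (bound_ml_dl + dissolved_ml_dl) / 100
}

#' Retinal oxygen extraction
#'
#' The amount of oxygen the retinal circulation extracts per unit time: the
#' arteriovenous oxygen-content difference times total retinal blood flow,
#' \eqn{extO_2 = (cO_{2,CRA} - cO_{2,CRV}) \cdot Q}, in \eqn{\mu}l O2/min.
#'
#' @param c_cra Oxygen content of the central retinal artery, mL O2 per mL
#'   blood.
#' @param c_crv Oxygen content of the central retinal vein, mL O2 per mL
#'   blood.
#' @param trbf_ul_min Total retinal blood flow Q in \eqn{\mu}l/min.
#' @return Oxygen extraction in \eqn{\mu}l O2/min (negative if venous
#'   content exceeds arterial, which is non-physiologic).
#' @export
oxygen_extraction <- function(c_cra, c_crv, trbf_ul_min) {
  stopifnot(is.numeric(c_cra), is.numeric(c_crv), is.numeric(trbf_ul_min))
  if (any(trbf_ul_min < 0)) {
    stop("oxygen_extraction: negative blood flow", call. = FALSE)
  }
  (c_cra - c_crv) * trbf_ul_min
}

#' Full oximetry analysis of one eye's vessel table
#'
#' Runs the oxygen-extraction model end to end for one eye: distance-correct
#' per-vessel saturations, average corrected arterial saturations into the
#' central artery saturation, flow-weight corrected venous saturations into
#' the central vein saturation, convert both to oxygen contents, and
#' multiply the arteriovenous content difference by total retinal blood
#' flow.
#'
#' Flow weights for the venous mixing use the measured per-vein flows of
#' `flow`; saturations of all vessels carrying a measurement are used, not
#' only those above the flow caliper threshold.
#'
#' @param vessels Vessel table as in [total_retinal_blood_flow()], with
#'   additional columns `sat_measured` (fraction) and `dist_mm`.
#' @param flow A `flow_result` from [total_retinal_blood_flow()] for the
#'   same table.
#' @param params An [oxygen_model_params()] object.
#' @return An object of class `oxygen_profile`: list with `sa_cra`,
#'   `sa_crv`, `c_cra`, `c_crv` (mL O2/mL), `ext_o2` (\eqn{\mu}l O2/min)
#'   and `trbf_used` (\eqn{\mu}l/min).
#' @export
analyze_oximetry <- function(vessels, flow, params = oxygen_model_params()) {
  stopifnot(is.data.frame(vessels), inherits(flow, "flow_result"),
            all(c("kind", "sat_measured", "dist_mm") %in% names(vessels)))
  cs <- correct_saturation(vessels$sat_measured, vessels$dist_mm,
                           params$sat_distance_coeff)
  is_a <- vessels$kind == "A"
  is_v <- vessels$kind == "V"
  if (!any(is_a) || !any(is_v)) {
    stop("analyze_oximetry: need saturations for both arteries and veins",
         call. = FALSE)
  }
  pv <- flow$per_vessel
  vein_flows <- pv$flow_ul_min[pv$kind == "V"]
  sa_cra <- central_artery_saturation(cs[is_a])
  sa_crv <- central_vein_saturation(cs[is_v], vein_flows)
  c_cra <- oxygen_content(sa_cra, params)
  c_crv <- oxygen_content(sa_crv, params)
  out <- list(
    sa_cra = sa_cra, sa_crv = sa_crv,
    c_cra = c_cra, c_crv = c_crv,
    ext_o2 = oxygen_extraction(c_cra, c_crv, flow$trbf),
    trbf_used = flow$trbf
  )
  class(out) <- "oxygen_profile"
  out
}

#' @export
print.oxygen_profile <- function(x, ...) {
  cat(sprintf("SaO2 CRA %.3f, CRV %.3f; contents %.4f / %.4f mL O2/mL\n",
              x$sa_cra, x$sa_crv, x$c_cra, x$c_crv))
  cat(sprintf("Oxygen extraction %.3f ul O2/min at Q = %.2f ul/min\n",
              x$ext_o2, x$trbf_used))
  invisible(x)
}
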