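#' Time-average a Doppler phase-difference series
#'
#' Averages a recorded phase-difference series over whole cardiac pulse
#' cycles. When a pulse period hint is supplied, the mean is taken over the
#' largest integer number of cycles that fits into the recording, so that a
#' partially sampled final cycle does not bias the average; without a hint
#' the full series is used.
#'
#' @param values Numeric vector of phase differences (radians), ordered in
#'   time and uniformly sampled.
#' @param duration_s Total duration of the series in seconds.
#' @param pulse_period_s Optional pulse period hint in seconds. When given,
#'   `duration_s` must cover at least one full period.
#' @return Mean phase difference in radians.
#' @export
#' @examples
#' average_phase(rep(0.5, 100), duration_s = 2)
average_phase <- function(values, duration_s, pulse_period_s = NULL) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("average_phase: empty or non-numeric phase series", call. = FALSE)
  }
  stopifnot(is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  if (is.null(pulse_period_s)) {
    return(mean(values))
  }
  stopifnot(is.numeric(pulse_period_s), pulse_period_s > 0)
  n_cycles <- floor(duration_s / pulse_period_s)
  if (n_cycles < 1) {
    stop("average_phase: series shorter than one pulse cycle (",
         signif(duration_s, 4), " s < ", signif(pulse_period_s, 4),
         " s); pulse averaging needs at least one full cycle",
         call. = FALSE)
  }
  # samples are uniform over duration_s; keep those within whole cycles
  n_keep <- floor(length(values) * n_cycles * pulse_period_s / duration_s)
  n_keep <- max(1L, min(length(values), n_keep))
  mean(values[seq_len(n_keep)])
}

#' Absolute blood velocity from a bidirectional Doppler phase difference
#'
#' Converts the phase-shift difference between the two probe beams of a
#' dual-beam Doppler OCT system into absolute blood velocity:
#' \deqn{V_{abs} = \left| \frac{\Delta\Phi \, \lambda}
#'   {4\pi \, n \, \tau \, \Delta\alpha \, \cos\beta} \right|}
#' The sign of the phase difference encodes flow direction relative to the
#' detection plane and is discarded: downstream flow totals are summed by
#' vessel kind, not by sign.
#'
#' @param dphi Phase difference \eqn{\Delta\Phi} in radians (scalar or
#'   vector).
#' @param const A [doct_constants()] object.
#' @param beta_deg Optional per-vessel override of the Doppler angle in
#'   degrees; defaults to the angle stored in `const`.
#' @return Absolute velocity in m/s, same length as `dphi`.
#' @export
#' @examples
#' k <- doct_constants(wavelength_m = 8e-7, tau_s = 1e-4,
#'                     n_blood = 1.35, dalpha_rad = 0.01, beta_deg = 0)
#' doppler_velocity(0.5, k)  # ~0.0236 m/s
doppler_velocity <- function(dphi, const, beta_deg = NULL) {
  stopifnot(inherits(const, "doct_constants"), is.numeric(dphi))
  beta <- if (is.null(beta_deg)) const$beta_deg else beta_deg
  cb <- cos(beta * pi / 180)
  if (any(abs(cb) <= const$cos_beta_floor)) {
    stop("doppler_velocity: |cos(beta)| at or below floor (",
         const$cos_beta_floor, "); angle-degenerate geometry", call. = FALSE)
  }
  abs(dphi * const$wavelength_m /
        (4 * pi * const$n_blood * const$tau_s * const$dalpha_rad * cb))
}

#' Volumetric flow of a single vessel
#'
#' Cross-section times velocity, assuming a circular lumen:
#' \eqn{Q = \frac{D^2}{4}\pi \, V_{abs}}, returned in \eqn{\mu}l/min.
#'
#' @param diameter_um Lumen diameter in micrometres (scalar or vector).
#' @param velocity_m_s Mean absolute velocity in m/s.
#' @return Flow in microlitres per minute.
#' @export
#' @examples
#' vessel_flow(100, 0.02358)  # ~11.1 ul/min
vessel_flow <- function(diameter_um, velocity_m_s) {
  stopifnot(is.numeric(diameter_um), is.numeric(velocity_m_s))
  if (any(diameter_um <= 0)) {
    stop("vessel_flow: diameter must be positive", call. = FALSE)
  }
  if (any(velocity_m_s < 0)) {
    stop("vessel_flow: velocity must be non-negative (use absolute velocity)",
         call. = FALSE)
  }
  d_m <- diameter_um * 1e-6
  q_m3_s <- (d_m^2 / 4) * pi * velocity_m_s
  q_m3_s * 1e9 * 60  # m^3/s -> ul/min
}

#' Total retinal blood flow from a per-eye vessel table
#'
#' Computes per-vessel absolute velocities and volumetric flows for all
#' measured peripapillary vessels of one eye, sums them by kind into the
#' arterial and venous totals, and reports total retinal blood flow as the
#' mean of the two. Vessels narrower than `min_diameter_um` (default 40
#' micrometres) are excluded from the totals, mirroring the caliper
#' threshold of the flow measurement protocol; the cut is strict, a vessel
#' exactly at the threshold is kept.
#'
#' @param vessels Data frame with one row per vessel and columns
#'   `vessel_id`, `kind` (`"A"` for artery, `"V"` for vein), `diameter_um`,
#'   and either `dphi_rad` (pre-averaged phase difference, radians) or
#'   `velocity_m_s`. An optional `beta_deg` column overrides the Doppler
#'   angle per vessel.
#' @param const A [doct_constants()] object (required when velocities are
#'   derived from `dphi_rad`).
#' @param min_diameter_um Caliper threshold in micrometres; vessels with
#'   `diameter_um < min_diameter_um` are excluded.
#' @return An object of class `flow_result`: a list with `per_vessel` (the
#'   input table augmented with `velocity_m_s`, `flow_ul_min` and
#'   `included`), `trbf_arterial`, `trbf_venous` and `trbf`
#'   (all \eqn{\mu}l/min), and `n_excluded`.
#' @export
total_retinal_blood_flow <- function(vessels, const = NULL,
                                     min_diameter_um = 40) {
  stopifnot(is.data.frame(vessels), nrow(vessels) > 0,
            all(c("kind", "diameter_um") %in% names(vessels)))
  if (!all(vessels$kind %in% c("A", "V"))) {
    stop("total_retinal_blood_flow: kind must be 'A' or 'V'", call. = FALSE)
  }
  if (any(vessels$diameter_um <= 0)) {
    stop("total_retinal_blood_flow: non-positive vessel diameter",
         call. = FALSE)
  }
  v <- vessels
  if (!("velocity_m_s" %in% names(v))) {
    if (!("dphi_rad" %in% names(v))) {
      stop("total_retinal_blood_flow: need dphi_rad or velocity_m_s column",
           call. = FALSE)
    }
    if (is.null(const)) {
      stop("total_retinal_blood_flow: doct_constants required to convert ",
           "phase to velocity", call. = FALSE)
    }
    if ("beta_deg" %in% names(v)) {
      beta <- ifelse(is.na(v$beta_deg), const$beta_deg, v$beta_deg)
      v$velocity_m_s <- doppler_velocity(v$dphi_rad, const, beta_deg = beta)
    } else {
      v$velocity_m_s <- doppler_velocity(v$dphi_rad, const)
    }
  }
  v$velocity_m_s <- abs(v$velocity_m_s)
  v$flow_ul_min <- vessel_flow(v$diameter_um, v$velocity_m_s)
  v$included <- v$diameter_um >= min_diameter_um

  kept <- v[v$included, , drop = FALSE]
  if (!any(kept$kind == "A") || !any(kept$kind == "V")) {
    stop("total_retinal_blood_flow: need at least one artery and one vein ",
         "at or above ", min_diameter_um, " um (incomplete circulation)",
         call. = FALSE)
  }
  trbf_a <- sum(kept$flow_ul_min[kept$kind == "A"])
  trbf_v <- sum(kept$flow_ul_min[kept$kind == "V"])
  out <- list(
    per_vessel = v,
    trbf_arterial = trbf_a,
    trbf_venous = trbf_v,
    trbf = (trbf_a + trbf_v) / 2,
    n_excluded = sum(!v$included)
  )
  class(out) <- "flow_result"
  out
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf(
    "Total retinal blood flow: %.2f ul/min (arterial %.2f, venous %.2f)\n",
    x$trbf, x$trbf_arterial, x$trbf_venous))
  cat(sprintf("  %d vessels, %d excluded below caliper threshold\n",
              nrow(x$per_vessel), x$n_excluded))
  invisible(x)
}
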