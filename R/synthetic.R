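#' Synthetic cohort configuration
#'
#' Generating distributions for a three-group synthetic study (MS eyes
#' with and without a history of optic neuritis, and healthy controls)
#' with the statistical structure the analysis assumes: group-shifted
#' total retinal blood flow, arterial calibers and venous saturations,
#' mass-conserving per-eye vasculature, and group-shifted structural and
#' angiographic parameters. Group-level defaults follow the group means
#' and standard deviations the study design targets; measurement noise is
#' additive Gaussian on the observables (diameters, phases, saturations).
#'
#' All group-indexed fields are ordered `MS_ON`, `MS_noON`, `healthy`.
#'
#' @param n_per_group Eyes per group.
#' @param trbf_mean,trbf_sd Per-group total retinal blood flow
#'   distribution, \eqn{\mu}l/min.
#' @param artery_diam_mean Per-group median artery caliber, \eqn{\mu}m
#'   (lognormal).
#' @param vein_diam_mean Per-group median vein caliber before the
#'   mass-conservation rescaling, \eqn{\mu}m.
#' @param diam_sdlog Lognormal sdlog of vessel calibers.
#' @param n_vessels_range Range (inclusive) of the per-eye count of
#'   arteries and of veins.
#' @param sat_a_mean,sat_a_vessel_sd Arterial saturation: mean and
#'   per-vessel spread.
#' @param sat_v_mean Per-group venous saturation means.
#' @param sat_v_eye_sd,sat_v_vessel_sd Between-eye and per-vessel venous
#'   saturation spread.
#' @param artery_velocity_mean,artery_velocity_sd Relative artery velocity
#'   draw (m/s) before flow rescaling.
#' @param vein_velocity_mean,vein_velocity_sd Vein velocities, m/s.
#' @param noise_diam_sd_um,noise_phase_sd_rad,noise_sat_sd Additive
#'   measurement-noise SDs on diameter, averaged phase and saturation.
#'   Set all to 0 for noise-free cohorts.
#' @param rnflt_mean,rnflt_eye_sd Per-group global RNFLT distribution,
#'   \eqn{\mu}m; `rnflt_profile_sd` is the within-profile sample spread
#'   and `rnflt_n_samples` the ring-scan sample count.
#' @param rnflt_profile_sd,rnflt_n_samples See above.
#' @param gcipl_mean,gcipl_eye_sd Per-group GCIPL distribution, \eqn{\mu}m;
#'   split between GCL and IPL by `gcl_share`.
#' @param gcl_share Fraction of GCIPL assigned to the GCL.
#' @param capillary_fraction_mean,capillary_fraction_eye_sd Per-group
#'   bright-pixel fraction of the angiogram speckle background.
#' @param octa_n_vessels Large vessels rendered per angiogram.
#' @param octa_size_px,octa_scan_width_mm Angiogram raster size and field
#'   width (pixel scale is their ratio).
#' @param octa_noise_sd Gaussian intensity noise on the angiogram.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(MS_ON = 16, MS_noON = 16, healthy = 18),
                          trbf_mean = c(33.2, 38.3, 37.2),
                          trbf_sd = c(6.0, 4.6, 4.7),
                          artery_diam_mean = c(100, 100, 108),
                          vein_diam_mean = c(104, 104, 106),
                          diam_sdlog = 0.13,
                          n_vessels_range = c(6, 8),
                          sat_a_mean = 0.95,
                          sat_a_vessel_sd = 0.01,
                          sat_v_mean = c(0.60, 0.57, 0.55),
                          sat_v_eye_sd = 0.025,
                          sat_v_vessel_sd = 0.015,
                          artery_velocity_mean = 0.012,
                          artery_velocity_sd = 0.003,
                          vein_velocity_mean = 0.011,
                          vein_velocity_sd = 0.002,
                          noise_diam_sd_um = 2,
                          noise_phase_sd_rad = 5e-4,
                          noise_sat_sd = 0.02,
                          rnflt_mean = c(80.7, 96.8, 100.0),
                          rnflt_eye_sd = c(14.0, 8.9, 9.5),
                          rnflt_profile_sd = 15,
                          rnflt_n_samples = 256,
                          gcipl_mean = c(73.7, 92.2, 93.8),
                          gcipl_eye_sd = c(14.6, 9.4, 7.2),
                          gcl_share = 0.57,
                          capillary_fraction_mean = c(0.46, 0.49, 0.52),
                          capillary_fraction_eye_sd = 0.03,
                          octa_n_vessels = 4,
                          octa_size_px = 384,
                          octa_scan_width_mm = 4.4,
                          octa_noise_sd = 0.12) {
  groups <- c("MS_ON", "MS_noON", "healthy")
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1),
            length(trbf_mean) == 3L, length(trbf_sd) == 3L,
            all(trbf_sd >= 0), all(trbf_mean > 0),
            length(sat_v_mean) == 3L, all(sat_v_mean > 0 & sat_v_mean < 1),
            sat_a_mean > 0, sat_a_mean < 1,
            all(c(noise_diam_sd_um, noise_phase_sd_rad, noise_sat_sd) >= 0),
            n_vessels_range[1] >= 1, n_vessels_range[2] >= n_vessels_range[1],
            gcl_share > 0, gcl_share < 1,
            all(capillary_fraction_mean >= 0 & capillary_fraction_mean <= 1))
  names(n_per_group) <- groups
  cfg <- as.list(environment())
  cfg$groups <- groups
  class(cfg) <- "cohort_config"
  cfg
}

# internal: index of a group label in the config ordering
group_index <- function(cfg, group) {
  i <- match(group, cfg$groups)
  if (is.na(i)) {
    stop("unknown group label '", group, "'; expected one of ",
         paste(cfg$groups, collapse = ", "), call. = FALSE)
  }
  i
}

# internal: truncated normal by resampling (vectorised, simple)
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate one synthetic eye with recorded ground truth
#'
#' Draws one eye's vasculature for the given group: vessel counts,
#' calibers and velocities; arterial velocities are rescaled so arterial
#' flow totals the eye's drawn TRBF, and venous calibers are rescaled
#' (square root of the flow ratio) so venous outflow equals arterial
#' inflow exactly - mass conservation holds before noise. Ground truth
#' (TRBF, central saturations, oxygen contents, extraction, structural
#' summaries) is computed by running the analysis equations on the
#' noise-free observables; additive Gaussian measurement noise is then
#' applied to the recorded observables (diameters, averaged phases,
#' saturations).
#'
#' @param group Group label: `"MS_ON"`, `"MS_noON"` or `"healthy"`.
#' @param cfg A [cohort_config()].
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible in isolation. Leave `NULL` to consume the caller's RNG
#'   stream (as [generate_cohort()] does).
#' @param const A [doct_constants()] used to encode true velocities as
#'   phase differences.
#' @param params An [oxygen_model_params()] used for ground-truth oxygen
#'   contents.
#' @return List with `eye_id` (`NA`, set by the cohort generator),
#'   `group`, `vessels` (noisy observable table with columns `vessel_id`,
#'   `kind`, `diameter_um`, `dphi_rad`, `sat_measured`, `dist_mm`),
#'   `rnfl_profile_um`, `gcl_inner_um`, `ipl_inner_um`,
#'   `capillary_fraction`, and `truth` (noise-free TRBF and totals,
#'   central saturations, contents, extraction, structural means).
#' @export
generate_eye <- function(group, cfg = cohort_config(), seed = NULL,
                         const = doct_constants(),
                         params = oxygen_model_params()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  gi <- group_index(cfg, group)

  n_a <- sample(seq(cfg$n_vessels_range[1], cfg$n_vessels_range[2]), 1L)
  n_v <- sample(seq(cfg$n_vessels_range[1], cfg$n_vessels_range[2]), 1L)
  trbf_true <- rnorm_trunc(1, cfg$trbf_mean[gi], cfg$trbf_sd[gi], lo = 10)

  # arteries: calibers and relative velocities, rescaled to the eye's TRBF
  d_a <- stats::rlnorm(n_a, log(cfg$artery_diam_mean[gi]), cfg$diam_sdlog)
  d_a <- clamp(d_a, 60, 180)
  v_a <- rnorm_trunc(n_a, cfg$artery_velocity_mean, cfg$artery_velocity_sd,
                     lo = 0.003)
  q_a_raw <- vessel_flow(d_a, v_a)
  v_a <- v_a * trbf_true / sum(q_a_raw)

  # veins: calibers rescaled so venous outflow equals arterial inflow
  d_v <- stats::rlnorm(n_v, log(cfg$vein_diam_mean[gi]), cfg$diam_sdlog)
  d_v <- clamp(d_v, 60, 220)
  v_v <- rnorm_trunc(n_v, cfg$vein_velocity_mean, cfg$vein_velocity_sd,
                     lo = 0.002)
  q_v_raw <- vessel_flow(d_v, v_v)
  d_v <- d_v * sqrt(trbf_true / sum(q_v_raw))

  s_a <- clamp(stats::rnorm(n_a, cfg$sat_a_mean, cfg$sat_a_vessel_sd),
               0.85, 0.999)
  sv_eye <- rnorm_trunc(1, cfg$sat_v_mean[gi], cfg$sat_v_eye_sd,
                        lo = 0.35, hi = 0.80)
  s_v <- clamp(stats::rnorm(n_v, sv_eye, cfg$sat_v_vessel_sd), 0.30, 0.85)
  dist <- stats::runif(n_a + n_v, 0.5, 3.0)

  # noise-free observables: encode true velocities as phase differences
  dphi_true <- c(v_a, v_v) * (4 * pi * const$n_blood * const$tau_s *
                                const$dalpha_rad *
                                cos(const$beta_deg * pi / 180)) /
    const$wavelength_m
  clean <- data.frame(
    vessel_id = sprintf("%s%02d", rep(c("A", "V"), c(n_a, n_v)),
                        c(seq_len(n_a), seq_len(n_v))),
    kind = rep(c("A", "V"), c(n_a, n_v)),
    diameter_um = c(d_a, d_v),
    dphi_rad = dphi_true,
    sat_measured = c(s_a, s_v),
    dist_mm = dist,
    stringsAsFactors = FALSE
  )

  # ground truth: the analysis equations applied to noise-free observables
  flow_true <- total_retinal_blood_flow(clean, const)
  oxy_true <- analyze_oximetry(clean, flow_true, params)

  # structural inputs
  rn_eye <- rnorm_trunc(1, cfg$rnflt_mean[gi], cfg$rnflt_eye_sd[gi], lo = 30)
  rnfl_profile <- pmax(stats::rnorm(cfg$rnflt_n_samples, rn_eye,
                                    cfg$rnflt_profile_sd), 5)
  gcipl_eye <- rnorm_trunc(1, cfg$gcipl_mean[gi], cfg$gcipl_eye_sd[gi],
                           lo = 30)
  gcl_q <- pmax(stats::rnorm(4, gcipl_eye * cfg$gcl_share, 2), 5)
  ipl_q <- pmax(stats::rnorm(4, gcipl_eye * (1 - cfg$gcl_share), 2), 5)
  cap_frac <- clamp(stats::rnorm(1, cfg$capillary_fraction_mean[gi],
                                 cfg$capillary_fraction_eye_sd), 0.05, 0.95)

  # noisy observables
  noisy <- clean
  noisy$diameter_um <- noisy$diameter_um +
    stats::rnorm(nrow(noisy), 0, cfg$noise_diam_sd_um)
  noisy$dphi_rad <- noisy$dphi_rad +
    stats::rnorm(nrow(noisy), 0, cfg$noise_phase_sd_rad)
  noisy$sat_measured <- clamp(
    noisy$sat_measured + stats::rnorm(nrow(noisy), 0, cfg$noise_sat_sd),
    0, 1)

  list(
    eye_id = NA_character_,
    group = group,
    vessels = noisy,
    vessels_clean = clean,
    rnfl_profile_um = rnfl_profile,
    gcl_inner_um = gcl_q,
    ipl_inner_um = ipl_q,
    capillary_fraction = cap_frac,
    truth = list(
      trbf = flow_true$trbf,
      trbf_arterial = flow_true$trbf_arterial,
      trbf_venous = flow_true$trbf_venous,
      sa_cra = oxy_true$sa_cra,
      sa_crv = oxy_true$sa_crv,
      c_cra = oxy_true$c_cra,
      c_crv = oxy_true$c_crv,
      ext_o2 = oxy_true$ext_o2,
      rnflt = mean(rnfl_profile),
      gcipl = mean(gcl_q) + mean(ipl_q),
      capillary_fraction = cap_frac
    )
  )
}

#' Generate a full synthetic cohort
#'
#' Draws `cfg$n_per_group` eyes per group from a single seeded RNG stream,
#' so two runs with equal seeds are identical.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for all randomness.
#' @param const,params Passed to [generate_eye()].
#' @param with_images Also render one synthetic angiogram per eye (slower;
#'   sized by `cfg$octa_size_px`).
#' @return Object of class `synthetic_cohort`: list with `eyes` (list of
#'   eye records with assigned `eye_id`s), `cfg`, `const`, `params`,
#'   `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L,
                            const = doct_constants(),
                            params = oxygen_model_params(),
                            with_images = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  eyes <- list()
  k <- 0L
  for (g in cfg$groups) {
    for (i in seq_len(cfg$n_per_group[[g]])) {
      k <- k + 1L
      eye <- generate_eye(g, cfg, seed = NULL, const = const,
                          params = params)
      eye$eye_id <- sprintf("%s_%02d", g, i)
      if (with_images) {
        im <- generate_octa_image(
          size_px = cfg$octa_size_px,
          n_large_vessels = cfg$octa_n_vessels,
          capillary_fraction = eye$capillary_fraction,
          noise_sd = cfg$octa_noise_sd,
          scan_width_mm = cfg$octa_scan_width_mm
        )
        eye$image <- im$image
        eye$truth$large_vessel_mask <- im$truth$large_vessel_mask
      }
      eyes[[k]] <- eye
    }
  }
  structure(list(eyes = eyes, cfg = cfg, const = const, params = params,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  grp <- vapply(x$eyes, `[[`, character(1), "group")
  cat("Synthetic cohort:", length(x$eyes), "eyes (",
      paste(names(table(grp)), table(grp), sep = "=", collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

#' Render a synthetic en-face angiogram with known ground truth
#'
#' Builds a peripapillary angiogram phantom: a binary speckle background
#' whose bright-pixel fraction equals `capillary_fraction`, overlaid with
#' `n_large_vessels` bright curved tubes whose half-widths sit in the
#' caliber range the large-vessel detector targets. The support of the
#' rendered tubes is recorded as the true large-vessel mask. Tubes
#' alternate between predominantly horizontal and predominantly vertical
#' courses with sinusoidal meander, emulating vessels crossing the
#' peripapillary ring.
#'
#' @param size_px Raster side length (square image).
#' @param n_large_vessels Number of tubes to render.
#' @param capillary_fraction Fraction of bright background pixels in
#'   \eqn{[0, 1]}.
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param seed Optional seed for an isolated reproducible draw.
#' @param scan_width_mm Physical width of the field; sets the pixel scale.
#' @param halfwidth_range_px Tube half-width range in pixels.
#' @return List with `image` (an [octa_image()] with the disc centre at
#'   the raster centre) and `truth` (list with logical
#'   `large_vessel_mask` and `capillary_fraction`).
#' @export
generate_octa_image <- function(size_px = 384, n_large_vessels = 4,
                                capillary_fraction = 0.5, noise_sd = 0.12,
                                seed = NULL, scan_width_mm = 4.4,
                                halfwidth_range_px = c(3.5, 6)) {
  stopifnot(size_px >= 32, n_large_vessels >= 0,
            capillary_fraction >= 0, capillary_fraction <= 1,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(size_px)
  # dark / bright speckle levels: chosen close enough that, with the
  # default intensity noise, the two populations overlap as real
  # capillary-bed reflectance does - the mean-threshold binarization must
  # respond to threshold shifts, not just count a separated bright mode
  lo <- 0.20; hi <- 0.50
  bright <- matrix(stats::runif(n * n) < capillary_fraction, n, n)
  img <- matrix(lo, n, n)
  img[bright] <- hi
  true_mask <- matrix(FALSE, n, n)

  if (n_large_vessels > 0) {
    rowmat <- matrix(seq_len(n), n, n)
    for (k in seq_len(n_large_vessels)) {
      w <- stats::runif(1, halfwidth_range_px[1], halfwidth_range_px[2])
      offset <- stats::runif(1, 0.15 * n, 0.85 * n)
      slope <- stats::runif(1, -0.15, 0.15)
      amp <- stats::runif(1, 0.02 * n, 0.06 * n)
      period <- stats::runif(1, 0.8 * n, 1.6 * n)
      phase <- stats::runif(1, 0, 2 * pi)
      t <- seq_len(n)
      centre <- offset + slope * (t - n / 2) +
        amp * sin(2 * pi * t / period + phase)
      d <- abs(rowmat - matrix(centre, n, n, byrow = TRUE))
      # flat-top profile with a 1.5 px shoulder; support is the true mask
      prof <- clamp((w + 1.5 - d) / 1.5, 0, 1)
      if (k %% 2L == 0L) {  # alternate orientation
        d <- t(d); prof <- t(prof)
      }
      sup <- prof > 0
      true_mask <- true_mask | sup
      img <- pmax(img, 0.15 + 0.85 * prof)
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  }
  im <- octa_image(clamp(img, 0, 1), scan_width_mm / n,
                   c((n + 1) / 2, (n + 1) / 2))
  list(image = im,
       truth = list(large_vessel_mask = true_mask,
                    capillary_fraction = capillary_fraction))
}
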