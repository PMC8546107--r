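#' Read a simple key = value configuration file
#'
#' Minimal INI-style reader: one `key = value` pair per line, `#` starts a
#' comment, blank lines ignored. Values are returned as character and
#' coerced by the caller.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_kv_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  names(vals) <- trimws(vapply(kv, `[`, character(1), 2L))
  vals
}

# internal: write a named list/vector as key = value lines
write_kv_config <- function(x, path) {
  writeLines(sprintf("%s = %s", names(x), vapply(x, format, character(1))),
             path)
  invisible(path)
}

#' Read DOCT device constants from a key = value config
#'
#' Expects keys `wavelength_m`, `tau_s`, `n_blood`, `dalpha_rad`,
#' `beta_deg` (optionally `cos_beta_floor`).
#'
#' @param path Config file path.
#' @return A [doct_constants()].
#' @export
read_constants_config <- function(path) {
  cfg <- read_kv_config(path)
  need <- c("wavelength_m", "tau_s", "n_blood", "dalpha_rad", "beta_deg")
  if (!all(need %in% names(cfg))) {
    stop("constants config must define ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(cfg[intersect(names(cfg),
                               c(need, "cos_beta_floor"))], as.numeric)
  do.call(doct_constants, args)
}

#' Read a per-eye vessel measurement table
#'
#' CSV with columns `eye_id`, `vessel_id`, `kind` (`A`/`V`),
#' `diameter_um`, `dphi_rad` (or `velocity_m_s`), `sat_measured`,
#' `dist_mm`; optional `beta_deg`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_vessel_table <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "vessel_id", "kind", "diameter_um", "sat_measured",
            "dist_mm")
  if (!all(need %in% names(v)) ||
      !any(c("dphi_rad", "velocity_m_s") %in% names(v))) {
    stop("vessel table needs columns ", paste(need, collapse = ", "),
         " and dphi_rad or velocity_m_s", call. = FALSE)
  }
  v
}

#' Analyse one eye end to end
#'
#' Runs every per-eye stage on one eye record: total retinal blood flow,
#' the oxygen-extraction model, Knudtson vessel equivalents, structural
#' summaries and - when an angiogram is attached - the OCTA density
#' analysis.
#'
#' @param eye Eye record as produced by [generate_eye()] /
#'   [generate_cohort()] (fields `vessels`, `rnfl_profile_um`,
#'   `gcl_inner_um`, `ipl_inner_um`, optional `image`).
#' @param const A [doct_constants()].
#' @param params An [oxygen_model_params()].
#' @param octa_args List of arguments forwarded to [analyze_octa()].
#' @param use_true_mask Remove large vessels with the eye's ground-truth
#'   mask (when present) instead of running the Hessian detector; used to
#'   isolate the density stage in simulation studies.
#' @return One-row data frame of per-eye metrics: `eye_id`, `group`,
#'   `trbf`, `trbf_arterial`, `trbf_venous`, `sa_cra`, `sa_crv`,
#'   `ext_o2`, `crae`, `crve`, `avr`, `rnflt`, `gcipl`, `cd_percent`,
#'   `lvd_percent` (densities `NA` without an image).
#' @export
analyze_eye <- function(eye, const = doct_constants(),
                        params = oxygen_model_params(),
                        octa_args = list(), use_true_mask = FALSE) {
  flow <- total_retinal_blood_flow(eye$vessels, const)
  oxy <- analyze_oximetry(eye$vessels, flow, params)
  eq <- vessel_equivalents(eye$vessels)
  rnflt <- global_rnflt(eye$rnfl_profile_um)
  gc <- gcipl(eye$gcl_inner_um, eye$ipl_inner_um)
  cd <- NA_real_; lvd <- NA_real_
  if (!is.null(eye$image)) {
    mask <- NULL
    if (use_true_mask) {
      if (is.null(eye$truth$large_vessel_mask)) {
        stop("analyze_eye: use_true_mask requires a ground-truth mask",
             call. = FALSE)
      }
      mask <- eye$truth$large_vessel_mask
    }
    oc <- do.call(analyze_octa, c(list(img = eye$image, mask = mask),
                                  octa_args))
    cd <- oc$cd_percent
    lvd <- oc$lvd_percent
  }
  data.frame(
    eye_id = eye$eye_id, group = eye$group,
    trbf = flow$trbf, trbf_arterial = flow$trbf_arterial,
    trbf_venous = flow$trbf_venous,
    sa_cra = oxy$sa_cra, sa_crv = oxy$sa_crv, ext_o2 = oxy$ext_o2,
    crae = eq$crae_um, crve = eq$crve_um, avr = eq$avr,
    rnflt = rnflt, gcipl = gc,
    cd_percent = cd, lvd_percent = lvd,
    stringsAsFactors = FALSE
  )
}

#' Run the full study analysis on a cohort
#'
#' The end-to-end analysis: every eye is analysed with [analyze_eye()]
#' (eyes whose analysis fails are quarantined with a logged reason and
#' excluded from summaries), per-group descriptive statistics are
#' tabulated, and each metric is compared across groups with the omnibus
#' ANOVA, Levene's test and - where the omnibus test is significant -
#' the planned pairwise contrasts.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a bare
#'   list of eye records.
#' @param const,params Analysis constants; default to those stored in the
#'   cohort when present.
#' @param alpha Significance level for the contrast gate.
#' @param metrics Metric columns to compare across groups.
#' @param octa_args,use_true_mask Passed to [analyze_eye()].
#' @param out_dir Optional directory; when given, writes
#'   `per_eye_metrics.csv`, `group_summary.csv`, `tests.csv` and
#'   `quarantine.csv` (all floating point at 6 significant digits).
#' @return Object of class `study_result`: list with `per_eye` (data
#'   frame), `group_summary`, `tests` (one row per metric x test),
#'   `comparisons` (full [compare_groups()] output per metric) and
#'   `quarantined` (data frame of eye_id/reason).
#' @export
run_study <- function(cohort, const = NULL, params = NULL, alpha = 0.05,
                      metrics = c("trbf", "ext_o2", "crae", "crve", "avr",
                                  "rnflt", "gcipl", "cd_percent",
                                  "lvd_percent"),
                      octa_args = list(), use_true_mask = FALSE,
                      out_dir = NULL) {
  eyes <- if (inherits(cohort, "synthetic_cohort")) cohort$eyes else cohort
  stopifnot(is.list(eyes), length(eyes) > 0)
  if (is.null(const)) {
    const <- if (inherits(cohort, "synthetic_cohort")) cohort$const
             else doct_constants()
  }
  if (is.null(params)) {
    params <- if (inherits(cohort, "synthetic_cohort")) cohort$params
              else oxygen_model_params()
  }

  rows <- list()
  quarantined <- data.frame(eye_id = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  for (eye in eyes) {
    res <- tryCatch(
      analyze_eye(eye, const, params, octa_args = octa_args,
                  use_true_mask = use_true_mask),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      quarantined <- rbind(quarantined, data.frame(
        eye_id = if (is.null(eye$eye_id)) NA_character_ else eye$eye_id,
        reason = conditionMessage(res), stringsAsFactors = FALSE))
      message("run_study: quarantined eye ", eye$eye_id, ": ",
              conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    stop("run_study: every eye failed analysis", call. = FALSE)
  }
  per_eye <- do.call(rbind, rows)

  comparisons <- list()
  summary_rows <- list()
  test_rows <- list()
  for (m in metrics) {
    if (!m %in% names(per_eye)) next
    vals <- per_eye[[m]]
    if (all(is.na(vals))) next
    groups <- split(vals[!is.na(vals)], per_eye$group[!is.na(vals)])
    groups <- groups[order(match(names(groups),
                                 c("MS_ON", "MS_noON", "healthy")))]
    cmp <- compare_groups(groups, alpha = alpha)
    comparisons[[m]] <- cmp
    summary_rows[[m]] <- cbind(metric = m, cmp$summary)
    tr <- data.frame(metric = m, test = "anova",
                     statistic = cmp$anova$statistic,
                     p_value = cmp$anova$p_value, stringsAsFactors = FALSE)
    tr <- rbind(tr, data.frame(metric = m, test = "levene",
                               statistic = cmp$levene$statistic,
                               p_value = cmp$levene$p_value))
    if (!is.null(cmp$contrasts)) {
      tr <- rbind(tr, data.frame(
        metric = m,
        test = paste0("contrast_", cmp$contrasts$group1, "_vs_",
                      cmp$contrasts$group2),
        statistic = cmp$contrasts$statistic,
        p_value = cmp$contrasts$p_value))
    }
    test_rows[[m]] <- tr
  }
  out <- list(
    per_eye = per_eye,
    group_summary = do.call(rbind, c(summary_rows,
                                     list(make.row.names = FALSE))),
    tests = do.call(rbind, c(test_rows, list(make.row.names = FALSE))),
    comparisons = comparisons,
    quarantined = quarantined,
    alpha = alpha
  )
  class(out) <- "study_result"
  if (!is.null(out_dir)) write_study_result(out, out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study result:", nrow(x$per_eye), "eyes analysed,",
      nrow(x$quarantined), "quarantined\n")
  om <- x$tests[x$tests$test == "anova", c("metric", "statistic", "p_value")]
  if (nrow(om)) {
    cat("Omnibus ANOVA:\n")
    for (i in seq_len(nrow(om))) {
      cat(sprintf("  %-12s F = %7.3f, p = %.4g\n", om$metric[i],
                  om$statistic[i], om$p_value[i]))
    }
  }
  invisible(x)
}

# internal: CSV writers with 6 significant digits on floats
write_study_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  utils::write.csv(fmt(result$per_eye),
                   file.path(out_dir, "per_eye_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(result$group_summary),
                   file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(result$tests), file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  utils::write.csv(result$quarantined,
                   file.path(out_dir, "quarantine.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Write a synthetic study to disk in the package's exchange formats
#'
#' Materialises a generated cohort as the plain-text inputs the analysis
#' consumes: a combined vessel table CSV, structural CSVs (ring-scan
#' profiles long-format, ETDRS quadrant table), a device-constants
#' config, a group roster, the ground-truth table, and - when images were
#' generated - one grayscale PNG plus geometry sidecar per eye.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eyes <- cohort$eyes

  vessels <- do.call(rbind, lapply(eyes, function(e) {
    cbind(eye_id = e$eye_id, e$vessels)
  }))
  utils::write.csv(vessels, file.path(dir, "vessels.csv"),
                   row.names = FALSE)

  rnfl <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id,
               sample_idx = seq_along(e$rnfl_profile_um),
               thickness_um = e$rnfl_profile_um)
  }))
  utils::write.csv(rnfl, file.path(dir, "rnfl_profiles.csv"),
                   row.names = FALSE)

  quad <- c("superior", "nasal", "inferior", "temporal")
  etdrs <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id, quadrant = quad,
               gcl_um = e$gcl_inner_um, ipl_um = e$ipl_inner_um)
  }))
  utils::write.csv(etdrs, file.path(dir, "etdrs_inner.csv"),
                   row.names = FALSE)

  roster <- data.frame(
    eye_id = vapply(eyes, `[[`, character(1), "eye_id"),
    group = vapply(eyes, `[[`, character(1), "group"))
  utils::write.csv(roster, file.path(dir, "eyes.csv"), row.names = FALSE)

  truth <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id,
               as.data.frame(e$truth[setdiff(names(e$truth),
                                             "large_vessel_mask")]))
  }))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)

  k <- cohort$const
  write_kv_config(list(wavelength_m = k$wavelength_m, tau_s = k$tau_s,
                       n_blood = k$n_blood, dalpha_rad = k$dalpha_rad,
                       beta_deg = k$beta_deg),
                  file.path(dir, "doct_constants.cfg"))

  has_img <- vapply(eyes, function(e) !is.null(e$image), logical(1))
  if (any(has_img)) {
    img_dir <- file.path(dir, "octa")
    dir.create(img_dir, showWarnings = FALSE)
    for (e in eyes[has_img]) {
      p <- file.path(img_dir, paste0(e$eye_id, ".png"))
      png::writePNG(e$image$pixels, p)
      write_kv_config(list(pixel_scale_mm = e$image$pixel_scale_mm,
                           disc_center_row = e$image$disc_center[1],
                           disc_center_col = e$image$disc_center[2]),
                      paste0(p, ".cfg"))
    }
  }
  invisible(dir)
}

#' Read a study directory back into a cohort object
#'
#' Inverse of [write_study()] for the plain-text parts (vessel table,
#' structural tables, constants, roster, angiogram PNGs when present).
#' Ground truth, if on disk, is attached per eye.
#'
#' @param dir Study directory.
#' @return A list of eye records wrapped as class `synthetic_cohort`
#'   (without generator config).
#' @export
read_study <- function(dir) {
  vessels <- read_vessel_table(file.path(dir, "vessels.csv"))
  roster <- utils::read.csv(file.path(dir, "eyes.csv"),
                            stringsAsFactors = FALSE)
  rnfl <- utils::read.csv(file.path(dir, "rnfl_profiles.csv"),
                          stringsAsFactors = FALSE)
  etdrs <- utils::read.csv(file.path(dir, "etdrs_inner.csv"),
                           stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL
  const <- read_constants_config(file.path(dir, "doct_constants.cfg"))

  eyes <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$eye_id[i]
    e <- list(
      eye_id = id,
      group = roster$group[i],
      vessels = vessels[vessels$eye_id == id,
                        setdiff(names(vessels), "eye_id")],
      rnfl_profile_um = rnfl$thickness_um[rnfl$eye_id == id],
      gcl_inner_um = etdrs$gcl_um[etdrs$eye_id == id],
      ipl_inner_um = etdrs$ipl_um[etdrs$eye_id == id]
    )
    img_path <- file.path(dir, "octa", paste0(id, ".png"))
    if (file.exists(img_path)) e$image <- read_octa_png(img_path)
    if (!is.null(truth)) {
      tr <- truth[truth$eye_id == id, , drop = FALSE]
      if (nrow(tr) == 1L) e$truth <- as.list(tr[, -1, drop = FALSE])
    }
    e
  })
  structure(list(eyes = eyes, const = const,
                 params = oxygen_model_params(), seed = NA_integer_),
            class = "synthetic_cohort")
}
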