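#' Knudtson central retinal vessel equivalent
#'
#' Summarises the calibers of the peripapillary arteries (or veins) into a
#' single central retinal artery (vein) equivalent using the revised
#' "big six" pairing scheme: the six largest widths are paired iteratively,
#' largest with smallest, each pair combining as
#' \eqn{k \sqrt{w_1^2 + w_2^2}} with branching coefficient k = 0.88 for
#' arteries and k = 0.95 for veins; an unpaired middle element carries to
#' the next round unchanged, and rounds repeat until a single value
#' remains.
#'
#' @param widths_um Vessel widths in micrometres; all must be positive.
#'   When more than six are supplied, only the six largest enter the
#'   calculation; fewer than six are used as-is with a warning.
#' @param kind `"artery"` or `"vein"`; selects the branching coefficient.
#' @return Equivalent caliber in micrometres.
#' @export
#' @examples
#' knudtson_equivalent(c(100, 100), "artery")  # 0.88 * 100 * sqrt(2)
knudtson_equivalent <- function(widths_um, kind = c("artery", "vein")) {
  kind <- match.arg(kind)
  if (length(widths_um) == 0L || !is.numeric(widths_um)) {
    stop("knudtson_equivalent: need at least one width", call. = FALSE)
  }
  if (any(widths_um <= 0) || any(!is.finite(widths_um))) {
    stop("knudtson_equivalent: widths must be positive and finite",
         call. = FALSE)
  }
  k <- if (kind == "artery") 0.88 else 0.95
  w <- sort(widths_um, decreasing = TRUE)
  if (length(w) > 6L) {
    w <- w[1:6]
  } else if (length(w) < 6L) {
    warning("knudtson_equivalent: only ", length(w),
            " widths supplied; the scheme is defined on the six largest",
            call. = FALSE)
  }
  while (length(w) > 1L) {
    n <- length(w)
    n_pairs <- n %/% 2L
    paired <- k * sqrt(w[seq_len(n_pairs)]^2 + w[n + 1L - seq_len(n_pairs)]^2)
    carry <- if (n %% 2L == 1L) w[n_pairs + 1L] else numeric(0)
    w <- sort(c(paired, carry), decreasing = TRUE)
  }
  w
}

#' Arterio-venous ratio
#'
#' Ratio of the central retinal artery equivalent to the central retinal
#' vein equivalent. Values below 1 are normal (veins are wider); arteriolar
#' narrowing lowers the ratio.
#'
#' @param crae_um Central retinal artery equivalent, micrometres.
#' @param crve_um Central retinal vein equivalent, micrometres; must be
#'   positive.
#' @return Dimensionless ratio.
#' @export
arterio_venous_ratio <- function(crae_um, crve_um) {
  stopifnot(is.numeric(crae_um), is.numeric(crve_um))
  if (any(crve_um <= 0)) {
    stop("arterio_venous_ratio: CRVE must be positive", call. = FALSE)
  }
  crae_um / crve_um
}

#' Vessel equivalents and AVR from a per-eye vessel table
#'
#' Convenience wrapper computing CRAE, CRVE and their ratio from the
#' diameters in one eye's vessel table.
#'
#' @param vessels Data frame with columns `kind` (`"A"`/`"V"`) and
#'   `diameter_um`.
#' @return List with `crae_um`, `crve_um`, `avr`, `n_arteries_used`,
#'   `n_veins_used` (capped at six).
#' @export
vessel_equivalents <- function(vessels) {
  stopifnot(is.data.frame(vessels),
            all(c("kind", "diameter_um") %in% names(vessels)))
  a <- vessels$diameter_um[vessels$kind == "A"]
  v <- vessels$diameter_um[vessels$kind == "V"]
  crae <- knudtson_equivalent(a, "artery")
  crve <- knudtson_equivalent(v, "vein")
  list(
    crae_um = crae, crve_um = crve,
    avr = arterio_venous_ratio(crae, crve),
    n_arteries_used = min(length(a), 6L),
    n_veins_used = min(length(v), 6L)
  )
}
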