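#' Global circumpapillary RNFL thickness
#'
#' The global retinal nerve fibre layer thickness is the unweighted mean of
#' the thickness samples around the circumpapillary ring scan.
#'
#' @param thickness_um Ordered numeric vector of RNFL thickness samples in
#'   micrometres; all non-negative.
#' @return Global RNFLT in micrometres.
#' @export
global_rnflt <- function(thickness_um) {
  if (length(thickness_um) == 0L || !is.numeric(thickness_um)) {
    stop("global_rnflt: empty thickness profile", call. = FALSE)
  }
  if (any(thickness_um < 0)) {
    stop("global_rnflt: negative thickness", call. = FALSE)
  }
  mean(thickness_um)
}

#' Ganglion cell plus inner plexiform layer thickness
#'
#' GCIPL summarises the macular ganglion cell complex as the sum of the
#' averaged GCL and averaged IPL thicknesses over the four inner (3 mm)
#' quadrants of the macula-centred ETDRS grid.
#'
#' @param gcl_inner_um Four GCL thicknesses (superior, nasal, inferior,
#'   temporal inner quadrants), micrometres.
#' @param ipl_inner_um Four IPL thicknesses of the same quadrants.
#' @return GCIPL in micrometres.
#' @export
#' @examples
#' gcipl(c(40, 42, 38, 44), c(30, 32, 28, 34))  # 41 + 31 = 72
gcipl <- function(gcl_inner_um, ipl_inner_um) {
  if (length(gcl_inner_um) != 4L || length(ipl_inner_um) != 4L ||
      anyNA(gcl_inner_um) || anyNA(ipl_inner_um)) {
    stop("gcipl: need complete GCL and IPL inner-quadrant quadruples",
         call. = FALSE)
  }
  if (any(gcl_inner_um < 0) || any(ipl_inner_um < 0)) {
    stop("gcipl: negative thickness", call. = FALSE)
  }
  mean(gcl_inner_um) + mean(ipl_inner_um)
}
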