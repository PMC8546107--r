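#' En-face OCT angiography image container
#'
#' Bundles a 2-D grayscale en-face angiogram with its isotropic pixel scale
#' and the optic-disc centre, the reference point for the annular
#' peripapillary region of interest. Pixel coordinates are R matrix
#' indices (1-based, row-major, origin top-left); distances are measured
#' between pixel centres.
#'
#' @param pixels Numeric matrix of intensities (arbitrary units).
#' @param pixel_scale_mm Side length of one pixel in mm (isotropic).
#' @param disc_center Numeric length-2 vector `(row, col)` of the disc
#'   centre, within the raster bounds.
#' @return Object of class `octa_image`.
#' @export
octa_image <- function(pixels, pixel_scale_mm, disc_center) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            nrow(pixels) > 0, ncol(pixels) > 0,
            is.numeric(pixel_scale_mm), length(pixel_scale_mm) == 1L,
            pixel_scale_mm > 0,
            is.numeric(disc_center), length(disc_center) == 2L)
  if (disc_center[1] < 1 || disc_center[1] > nrow(pixels) ||
      disc_center[2] < 1 || disc_center[2] > ncol(pixels)) {
    stop("octa_image: disc_center outside raster bounds", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_scale_mm = pixel_scale_mm,
                 disc_center = disc_center),
            class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("octa_image: %d x %d px, %.4f mm/px, disc at (%.0f, %.0f)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_scale_mm,
              x$disc_center[1], x$disc_center[2]))
  invisible(x)
}

#' Read an en-face angiogram from a grayscale PNG
#'
#' Reads an 8/16-bit grayscale PNG and attaches geometry from a sidecar
#' `key = value` config (keys `pixel_scale_mm`, `disc_center_row`,
#' `disc_center_col`; 1-based pixel indices). RGB input is averaged to
#' gray.
#'
#' @param path Path to the PNG file.
#' @param config_path Path to the sidecar config; defaults to
#'   `<path>.cfg`.
#' @return An [octa_image()].
#' @export
read_octa_png <- function(path, config_path = paste0(path, ".cfg")) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  cfg <- read_kv_config(config_path)
  need <- c("pixel_scale_mm", "disc_center_row", "disc_center_col")
  if (!all(need %in% names(cfg))) {
    stop("read_octa_png: sidecar config must define ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  octa_image(px, as.numeric(cfg[["pixel_scale_mm"]]),
             c(as.numeric(cfg[["disc_center_row"]]),
               as.numeric(cfg[["disc_center_col"]])))
}

#' Write a binary vessel mask as a PNG for visual QC
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

# internal: second-order Gaussian-derivative responses of an image at
# scale sigma (px), via separable kernels and EBImage FFT convolution.
# Returned derivatives are scale-normalised (multiplied by sigma^2) so
# responses are comparable across scales.
hessian_responses <- function(pixels, sigma) {
  hw <- max(2L, ceiling(4 * sigma))
  x <- seq(-hw, hw)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  # derivatives of the (normalised) 1-D Gaussian
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  kxx <- outer(g2, g)   # d2/drow2
  kyy <- outer(g, g2)   # d2/dcol2
  kxy <- outer(g1, g1)
  s2 <- sigma^2
  list(
    xx = s2 * EBImage::filter2(pixels, kxx, boundary = "replicate"),
    yy = s2 * EBImage::filter2(pixels, kyy, boundary = "replicate"),
    xy = s2 * EBImage::filter2(pixels, kxy, boundary = "replicate")
  )
}

# internal: single-scale Frangi vesselness for bright tubular structures.
# beta controls blob/line discrimination, c the structureness falloff
# (chosen adaptively as half the maximal Hessian norm at this scale).
frangi_single_scale <- function(pixels, sigma, beta = 0.5) {
  h <- hessian_responses(pixels, sigma)
  half_diff <- (h$xx - h$yy) / 2
  half_sum <- (h$xx + h$yy) / 2
  disc <- sqrt(half_diff^2 + h$xy^2)
  mu1 <- half_sum + disc
  mu2 <- half_sum - disc
  # order eigenvalues by absolute value: |l1| <= |l2|
  swap <- abs(mu1) > abs(mu2)
  l1 <- ifelse(swap, mu2, mu1)
  l2 <- ifelse(swap, mu1, mu2)
  s2 <- l1^2 + l2^2
  c_half <- sqrt(max(s2)) / 2
  if (c_half <= 0) {
    return(matrix(0, nrow(pixels), ncol(pixels)))
  }
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c_half^2)))
  v[l2 >= 0] <- 0  # bright ridges have strongly negative l2
  v
}

#' Hessian-based large-vessel mask of an en-face angiogram
#'
#' Detects the major retinal vessels on an en-face angiogram with a
#' multiscale Frangi-type vesselness filter: at each scale the image is
#' smoothed with a Gaussian of width \eqn{\sigma}, the Hessian eigenvalues
#' are combined into a tubularity response favouring bright line-like
#' structures, responses are scale-normalised and maximised over scales,
#' and the maximal response is thresholded at a fraction of its image-wide
#' maximum. The default scales target vessel calibers of roughly 6-14 px,
#' the large-vessel range on a 384-px, ~4.4 mm scan. An optional
#' morphological dilation closes the sliver of vessel boundary the
#' threshold tends to miss.
#'
#' @param img An [octa_image()] or a plain numeric matrix.
#' @param scales_px Gaussian scales \eqn{\sigma} in pixels.
#' @param threshold Mask threshold as a fraction of the maximal vesselness
#'   response, in (0, 1).
#' @param dilate_px Radius (px) of a disc brush used to dilate the binary
#'   mask; 0 disables dilation.
#' @param beta Frangi blob-discrimination parameter.
#' @return Object of class `vessel_mask`: list with logical `mask`,
#'   `scales_px`, `threshold` and the raw `response` matrix. A flat image
#'   yields an all-`FALSE` mask.
#' @export
large_vessel_mask <- function(img, scales_px = c(3, 4, 5, 6),
                              threshold = 0.15, dilate_px = 1,
                              beta = 0.5) {
  pixels <- if (inherits(img, "octa_image")) img$pixels else img
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            length(scales_px) > 0, all(scales_px > 0),
            threshold > 0, threshold < 1, dilate_px >= 0)
  response <- matrix(0, nrow(pixels), ncol(pixels))
  if (diff(range(pixels)) > 0) {
    for (s in scales_px) {
      response <- pmax(response, frangi_single_scale(pixels, s, beta))
    }
  }
  mx <- max(response)
  mask <- if (mx > 0) response >= threshold * mx else response > 0
  if (dilate_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  }
  structure(list(mask = mask, scales_px = scales_px,
                 threshold = threshold, response = response),
            class = "vessel_mask")
}

#' Annular peripapillary region of interest
#'
#' Builds the ring-shaped ROI centred on the optic disc that the density
#' metrics are evaluated in: a pixel belongs to the ROI iff the distance
#' from its centre to the disc centre lies in the half-open interval
#' `[inner radius, outer radius)`. Defaults are the 2.5 mm inner / 4 mm
#' outer diameters of the peripapillary ring. When the ring extends past
#' the field of view it is clipped at the raster bounds with a warning.
#'
#' @param dim_px Raster dimensions `c(rows, cols)`.
#' @param center Disc centre `(row, col)`, 1-based pixel indices.
#' @param pixel_scale_mm mm per pixel (isotropic).
#' @param inner_diameter_mm,outer_diameter_mm Ring diameters in mm;
#'   `outer > inner >= 0` required.
#' @return Logical matrix marking ROI membership.
#' @export
annulus_roi <- function(dim_px, center, pixel_scale_mm,
                        inner_diameter_mm = 2.5, outer_diameter_mm = 4.0) {
  stopifnot(length(dim_px) == 2L, all(dim_px >= 1),
            length(center) == 2L, pixel_scale_mm > 0)
  if (!(outer_diameter_mm > inner_diameter_mm) || inner_diameter_mm < 0) {
    stop("annulus_roi: need outer_diameter > inner_diameter >= 0",
         call. = FALSE)
  }
  r_in_px <- inner_diameter_mm / 2 / pixel_scale_mm
  r_out_px <- outer_diameter_mm / 2 / pixel_scale_mm
  dr <- seq_len(dim_px[1]) - center[1]
  dc <- seq_len(dim_px[2]) - center[2]
  d2 <- outer(dr^2, dc^2, "+")
  roi <- d2 >= r_in_px^2 & d2 < r_out_px^2
  # warn when the ring is clipped by the field of view
  margins <- c(center[1] - 1, dim_px[1] - center[1],
               center[2] - 1, dim_px[2] - center[2])
  if (any(margins < r_out_px)) {
    warning("annulus_roi: ring exceeds the field of view and is clipped ",
            "at the raster bounds", call. = FALSE)
  }
  roi
}

#' Capillary or large-vessel density in a region of interest
#'
#' Mean-value binarization density: after removing the pixels of the
#' other compartment, the remaining ROI pixels are thresholded at their own
#' mean intensity and density is the percentage of pixels at or above that
#' mean ("white"). In `capillary` mode the large-vessel mask is applied to
#' remove the major vessels; in `large_vessel` mode the inverted mask
#' removes the capillaries. The threshold is computed within the remaining
#' ROI only, so the measure is invariant under affine rescaling of the
#' intensities. Pixels exactly at the mean count as white, so a
#' constant-intensity region has density 100%.
#'
#' @param img An [octa_image()] or numeric matrix.
#' @param vessel_mask A `vessel_mask` from [large_vessel_mask()] or a
#'   logical matrix marking large-vessel pixels.
#' @param roi Logical ROI matrix, e.g. from [annulus_roi()].
#' @param mode `"capillary"` or `"large_vessel"`.
#' @return List with `density_percent`, `mode`, `roi_pixel_count` (pixels
#'   remaining after compartment removal) and `threshold` (the mean used).
#' @export
octa_density <- function(img, vessel_mask, roi,
                         mode = c("capillary", "large_vessel")) {
  mode <- match.arg(mode)
  pixels <- if (inherits(img, "octa_image")) img$pixels else img
  mask <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else vessel_mask
  stopifnot(is.matrix(pixels), is.logical(mask), is.logical(roi),
            all(dim(pixels) == dim(mask)), all(dim(pixels) == dim(roi)))
  keep <- if (mode == "capillary") roi & !mask else roi & mask
  n <- sum(keep)
  if (n == 0L) {
    stop("octa_density: no ROI pixels remain after removing the ",
         ifelse(mode == "capillary", "large-vessel", "capillary"),
         " compartment", call. = FALSE)
  }
  vals <- pixels[keep]
  thr <- mean(vals)
  list(
    density_percent = 100 * sum(vals >= thr) / n,
    mode = mode,
    roi_pixel_count = n,
    threshold = thr
  )
}

#' Capillary and large-vessel density of one angiogram
#'
#' Convenience wrapper running the full peripapillary density analysis:
#' large-vessel detection, annular ROI construction around the disc
#' centre, and mean-value binarization densities for both compartments.
#'
#' @param img An [octa_image()].
#' @param scales_px,threshold,dilate_px Passed to [large_vessel_mask()].
#' @param inner_diameter_mm,outer_diameter_mm Passed to [annulus_roi()].
#' @param mask Optional precomputed large-vessel mask (logical matrix or
#'   `vessel_mask`); when supplied the detector is skipped.
#' @return List with `cd_percent`, `lvd_percent`, `mask` (`vessel_mask` or
#'   the supplied mask) and `roi`.
#' @export
analyze_octa <- function(img, scales_px = c(3, 4, 5, 6), threshold = 0.15,
                         dilate_px = 1, inner_diameter_mm = 2.5,
                         outer_diameter_mm = 4.0, mask = NULL) {
  stopifnot(inherits(img, "octa_image"))
  if (is.null(mask)) {
    mask <- large_vessel_mask(img, scales_px = scales_px,
                              threshold = threshold, dilate_px = dilate_px)
  }
  roi <- annulus_roi(dim(img$pixels), img$disc_center, img$pixel_scale_mm,
                     inner_diameter_mm, outer_diameter_mm)
  cd <- octa_density(img, mask, roi, "capillary")
  lvd <- octa_density(img, mask, roi, "large_vessel")
  list(cd_percent = cd$density_percent,
       lvd_percent = lvd$density_percent,
       mask = mask, roi = roi)
}
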