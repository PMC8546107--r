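# tube image helper: straight bright tube through the raster centre at
# angle theta, half-width w, on a zero background
tube_image <- function(n, theta, w = 5) {
  rr <- row(matrix(0, n, n)) - (n + 1) / 2
  cc <- col(matrix(0, n, n)) - (n + 1) / 2
  d <- abs(rr * cos(theta) - cc * sin(theta))
  img <- matrix(0, n, n)
  img[d <= w] <- 1
  list(img = img, truth = d <= w)
}

test_that("a flat image yields an empty vessel mask", {
  m <- large_vessel_mask(matrix(0.5, 64, 64))
  expect_false(any(m$mask))
})

test_that("the vesselness mask recovers a bright tube on dark background", {
  tb <- tube_image(256, 0)
  m <- large_vessel_mask(tb$img)
  sens <- sum(m$mask & tb$truth) / sum(tb$truth)
  contam <- sum(m$mask & !tb$truth) / sum(!tb$truth)
  expect_gte(sens, 0.90)
  expect_lte(contam, 0.02)
})

test_that("tube detection is rotation-robust per unit length", {
  # compare mask pixel counts inside a central disc, where the 0 deg and
  # 45 deg tubes have identical in-disc length
  n <- 256
  rr <- row(matrix(0, n, n)) - (n + 1) / 2
  cc <- col(matrix(0, n, n)) - (n + 1) / 2
  disc <- sqrt(rr^2 + cc^2) <= 100
  c0 <- sum(large_vessel_mask(tube_image(n, 0)$img,
                              dilate_px = 0)$mask & disc)
  c45 <- sum(large_vessel_mask(tube_image(n, pi / 4)$img,
                               dilate_px = 0)$mask & disc)
  expect_lt(abs(c45 - c0) / c0, 0.10)
})

test_that("annulus ROI membership matches analytic area and a pixel loop", {
  # inner 0 is rejected (degenerate), so use a tiny inner diameter for the
  # whole-raster case via a huge outer one
  roi_all <- suppressWarnings(
    annulus_roi(c(21, 21), c(11, 11), pixel_scale_mm = 1,
                inner_diameter_mm = 0.001, outer_diameter_mm = 1000))
  expect_equal(sum(roi_all), 21 * 21 - 1)  # only the centre pixel excluded
  expect_false(roi_all[11, 11])

  # fine grid: pixel-count x pixel-area approaches the analytic ring area
  scale <- 0.01
  roi <- suppressWarnings(
    annulus_roi(c(501, 501), c(251, 251), scale,
                inner_diameter_mm = 2.5, outer_diameter_mm = 4.0))
  area_px <- sum(roi) * scale^2
  area_true <- pi * (2^2 - 1.25^2)
  expect_lt(abs(area_px - area_true) / area_true, 0.02)

  # random small instances vs the brute-force membership loop
  set.seed(60)
  for (i in 1:100) {
    dims <- sample(12:30, 2, replace = TRUE)
    ctr <- c(runif(1, 4, dims[1] - 3), runif(1, 4, dims[2] - 3))
    sc <- runif(1, 0.05, 0.3)
    d_in <- runif(1, 0.2, 1.5); d_out <- d_in + runif(1, 0.5, 2)
    roi <- suppressWarnings(annulus_roi(dims, ctr, sc, d_in, d_out))
    expect_equal(sum(roi),
                 oracle_annulus_count(dims, ctr, sc, d_in, d_out))
  }
  expect_error(annulus_roi(c(30, 30), c(15, 15), 0.1, 2, 2), "outer")
  expect_warning(annulus_roi(c(30, 30), c(15, 15), 0.1, 1, 4), "clipped")
})

test_that("mean-value binarization density behaves as specified", {
  # half bright, half dark, empty mask -> 50%
  img <- matrix(rep(c(1, 0), each = 32), 8, 8)
  roi <- matrix(TRUE, 8, 8)
  empty <- matrix(FALSE, 8, 8)
  d <- octa_density(img, empty, roi, "capillary")
  expect_equal(d$density_percent, 50)
  expect_equal(d$roi_pixel_count, 64)

  # constant region: every pixel equals the mean, >= rule -> 100%
  expect_equal(octa_density(matrix(0.3, 8, 8), empty, roi,
                            "capillary")$density_percent, 100)

  # ROI fully covered by the vessel mask in capillary mode errors
  full <- matrix(TRUE, 8, 8)
  expect_error(octa_density(img, full, roi, "capillary"), "remain")
  # and large-vessel mode with an empty mask errors symmetrically
  expect_error(octa_density(img, empty, roi, "large_vessel"), "remain")
})

test_that("density is invariant under affine intensity rescaling", {
  set.seed(61)
  img <- matrix(runif(400), 20, 20)
  roi <- matrix(TRUE, 20, 20)
  mask <- matrix(runif(400) < 0.2, 20, 20)
  base <- octa_density(img, mask, roi, "capillary")$density_percent
  for (i in 1:10) {
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(octa_density(a * img + b, mask, roi,
                              "capillary")$density_percent, base)
  }
})

test_that("density matches the brute-force pixel loop on random regions", {
  set.seed(62)
  for (i in 1:20) {
    img <- matrix(runif(144), 12, 12)
    roi <- matrix(runif(144) < 0.8, 12, 12)
    mask <- matrix(runif(144) < 0.25, 12, 12)
    if (!any(roi & !mask) || !any(roi & mask)) next
    expect_equal(octa_density(img, mask, roi, "capillary")$density_percent,
                 oracle_density_percent(img, roi & !mask))
    expect_equal(
      octa_density(img, mask, roi, "large_vessel")$density_percent,
      oracle_density_percent(img, roi & mask))
  }
})

test_that("removing a bright tube raises the capillary density", {
  set.seed(63)
  g <- generate_octa_image(192, 2, 0.4, scan_width_mm = 2.2)
  roi <- annulus_roi(dim(g$image$pixels), g$image$disc_center,
                     g$image$pixel_scale_mm, 1.0, 2.0)
  none <- matrix(FALSE, 192, 192)
  with_removal <- octa_density(g$image, g$truth$large_vessel_mask, roi,
                               "capillary")$density_percent
  without <- octa_density(g$image, none, roi, "capillary")$density_percent
  expect_gt(with_removal, without)
})

test_that("octa image round-trips through PNG with sidecar geometry", {
  set.seed(64)
  g <- generate_octa_image(48, 1, 0.5, 0.02, scan_width_mm = 0.55)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "eye.png")
  png::writePNG(g$image$pixels, p)
  writeLines(c(sprintf("pixel_scale_mm = %.10f", g$image$pixel_scale_mm),
               "disc_center_row = 24.5", "disc_center_col = 24.5"),
             paste0(p, ".cfg"))
  im2 <- read_octa_png(p)
  expect_equal(dim(im2$pixels), c(48, 48))
  expect_equal(im2$pixel_scale_mm, g$image$pixel_scale_mm)
  # 8-bit PNG quantisation bounds the round-trip error by 1/510
  expect_lt(max(abs(im2$pixels - g$image$pixels)), 2.1e-3)
  # mask QC export is readable and binary
  mp <- file.path(dir, "mask.png")
  write_mask_png(g$truth$large_vessel_mask, mp)
  back <- png::readPNG(mp) > 0.5
  expect_equal(back, g$truth$large_vessel_mask)
})
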