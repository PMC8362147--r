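test_that("eFoV Jaccard reproduces the analytic reference cases", {
  g <- scan_geometry()
  ring <- disc_mask(320, matrix = 128)
  expect_equal(as.numeric(jaccard_efov(ring, ring, g)), 1)

  left <- disc_mask(60, matrix = 128, center = c(-320, 0))
  right <- disc_mask(60, matrix = 128, center = c(320, 0))
  expect_equal(as.numeric(jaccard_efov(left, right, g)), 0)

  # two axis-aligned squares in the eFoV sharing half their area -> 1/3
  # (pixel-aligned 12x12 squares offset by half their width, all pixels
  # beyond the 250 mm sFoV radius)
  n <- 128
  sq <- function(i0) {
    m <- matrix(FALSE, n, n)
    m[i0:(i0 + 11), 59:70] <- TRUE
    as_test_mask(m)
  }
  a <- sq(108)
  b <- sq(114)
  expect_equal(as.numeric(jaccard_efov(a, b, g)), 1 / 3, tolerance = 1e-12)

  # both masks empty in the eFoV: defined as 1 with a flag
  inner <- disc_mask(100, matrix = 128)
  j <- jaccard_efov(inner, inner, g)
  expect_equal(as.numeric(j), 1)
  expect_true(attr(j, "empty_union"))

  small <- disc_mask(100, matrix = 64)
  expect_error(jaccard_efov(ring, small, g), "match")
})

test_that("eFoV metrics depend on physical positions, not grid indexing", {
  g <- scan_geometry()
  n <- 128
  sp <- 800 / n
  raster_at <- function(center, origin) {
    xs <- (seq_len(n) - (n + 1) / 2) * sp + origin[1]
    ys <- (seq_len(n) - (n + 1) / 2) * sp + origin[2]
    m <- list(values = array(outer(xs, ys, function(x, y)
      (x - center[1])^2 + (y - center[2])^2 <= 80^2), c(n, n, 1L)),
      pixel_spacing_mm = sp, slice_thickness_mm = 3, origin = origin)
    class(m) <- c("ct_mask", "ct_image")
    m
  }
  # same physical discs on a centered and on an off-center grid whose
  # pixel centers coincide (origin shifted by whole pixels)
  off <- c(8 * sp, -4 * sp)
  j_centered <- as.numeric(jaccard_efov(raster_at(c(300, 0), c(0, 0)),
                                        raster_at(c(290, 20), c(0, 0)), g))
  j_shifted <- as.numeric(jaccard_efov(raster_at(c(300, 0), off),
                                       raster_at(c(290, 20), off), g))
  expect_equal(j_shifted, j_centered)
  expect_gt(j_centered, 0)
  expect_lt(j_centered, 1)
})

test_that("object masks fill holes and keep the largest component", {
  img <- disc_image(150, 100, matrix = 128)
  img$values[60:68, 60:68, 1] <- -1000       # internal air hole
  img$values[2:4, 2:4, 1] <- 500             # disconnected speck
  m <- object_mask(img, -400)
  expect_true(all(m$values[60:68, 60:68, 1]))  # hole filled
  expect_false(any(m$values[2:4, 2:4, 1]))     # speck dropped
  # threshold monotonicity on a soft-boundary image
  soft <- binarize_object(img, sigma_mm = 20, threshold_hu = -400)
  softer <- binarize_object(img, sigma_mm = 20, threshold_hu = -100)
  expect_lte(sum(softer$values), sum(soft$values))
  expect_error(object_mask(disc_image(0, -1000, matrix = 32)),
               class = "efovct_empty_mask")
})

test_that("eFoV slice volumes match the analytic segment oracle", {
  g <- scan_geometry()
  inner <- disc_mask(100, matrix = 256)
  expect_equal(slice_efov_volume(inner, g), 0)

  body <- disc_mask(320, matrix = 512)
  body$slice_thickness_mm <- 10
  vol <- slice_efov_volume(body, g)
  annulus_cm3 <- pi * (320^2 - 250^2) * 10 / 1000
  expect_lt(abs(vol / annulus_cm3 - 1), 0.02)

  # additive over slices
  two <- body
  two$values <- array(rep(body$values, 2), c(dim(body$values)[1:2], 2))
  expect_equal(sum(slice_efov_volume(two, g)), 2 * vol)
})

test_that("volume RMSD matches hand-computed values", {
  expect_equal(volume_rmsd(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(volume_rmsd(c(10, 20), c(13, 16)), sqrt((9 + 16) / 2))
  expect_equal(volume_rmsd(c(10, 20), c(13, 16)),
               volume_rmsd(c(20, 10), c(16, 13)))
  expect_error(volume_rmsd(1:3, 1:2), "length")
})

test_that("ROI statistics average the cylinder they claim to", {
  img <- ct_image(array(42, c(64, 64, 5)), 4)
  st <- roi_hu_stats(img, c(0, 0))
  expect_equal(st$mean, 42)
  expect_equal(st$sd, 0)

  # two-valued ROI: voxel-count-weighted mean, enumerated independently
  img2 <- ct_image(array(0, c(64, 64, 5)), 4)
  img2$values[33:64, , ] <- 100
  st2 <- roi_hu_stats(img2, c(0, 0), radius_mm = 10, n_slices = 5)
  xs <- efovct:::image_axis(img2, 1)
  sel <- outer(xs^2, xs^2, `+`) <= 100
  manual <- mean(img2$values[, , 1][sel])
  expect_equal(st2$mean, manual)
  expect_equal(st2$n_voxels, 5 * sum(sel))

  expect_error(roi_hu_stats(img, c(500, 0)), "grid")
  expect_error(roi_hu_stats(ct_image(array(0, c(8, 8, 2)), 4), c(0, 0),
                            n_slices = 5), "slice range")
})

test_that("eFoV histograms conserve counts and track HU shifts", {
  g <- scan_geometry()
  img <- disc_image(320, 55, matrix = 256)
  mask <- disc_mask(320, matrix = 256)
  h <- efov_hu_histogram(img, mask, g, bin_width_hu = 10)
  xs <- efovct:::image_axis(img, 1)
  n_efov <- sum(mask$values[, , 1] & outer(xs^2, xs^2, `+`) > 250^2)
  expect_equal(sum(h$counts), n_efov)
  expect_equal(sum(h$counts > 0), 1)          # uniform region: single bin

  shifted <- img
  shifted$values <- img$values + 60
  h2 <- efov_hu_histogram(shifted, mask, g, bin_width_hu = 10)
  occ <- function(hh) hh$breaks[which(hh$counts > 0)]
  expect_equal(occ(h2), occ(h) + 60)

  inner <- disc_mask(100, matrix = 256)
  expect_error(efov_hu_histogram(img, inner, g),
               class = "efovct_empty_region")
})
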