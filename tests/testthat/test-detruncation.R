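# reduced-size truncated thorax used across detruncation tests
trunc_fixture <- function(n_angles = 180, matrix = 256) {
  g <- scan_geometry(n_angles = n_angles)
  ph <- make_thorax_phantom(thorax_spec(n_slices = 1),
                            pixel_spacing_mm = 800 / matrix)
  wide <- forward_project(ph$image, extend_geometry(g))
  list(g = g, ph = ph, wide = wide,
       meas = truncate_sinogram(wide, g))
}

test_that("projection mass is scale-equivariant and flags truncation", {
  fx <- trunc_fixture()
  mp <- projection_mass(fx$meas)
  expect_lt(min(mp$normalized), 1)          # truncated: mass drops below 1
  scaled <- fx$meas
  scaled$values <- scaled$values * 3
  mp3 <- projection_mass(scaled)
  expect_equal(mp3$mass, 3 * mp$mass, tolerance = 1e-12)
  expect_equal(mp3$normalized, mp$normalized, tolerance = 1e-12)
  zero <- fx$meas
  zero$values[] <- 0
  expect_error(projection_mass(zero), "all-zero")
})

test_that("untruncated projection mass matches the attenuation area integral", {
  fx <- trunc_fixture()
  mp <- projection_mass(fx$wide)
  mu_area <- sum(pmax(0.02 * (1 + fx$ph$image$values / 1000), 0)) *
    fx$ph$image$pixel_spacing_mm^2
  expect_lt(max(abs(mp$mass / mu_area - 1)), 0.005)
})

test_that("cosine detruncation restores mass consistency", {
  fx <- trunc_fixture(n_angles = 360)
  det <- cosine_detruncate(fx$meas)
  norm <- projection_mass(det$sinogram)$normalized
  expect_lt(max(abs(norm - 1)), 1e-3)
  expect_true(all(det$added_mass >= -1e-9))
  # measured channels bit-exact
  blk <- efovct:::centered_block(det$sinogram$geometry$n_channels,
                                 fx$g$n_channels)
  expect_identical(det$sinogram$values[, blk[1]:blk[2], ], fx$meas$values[, , ])
  # the extension has decayed to (near) zero at the bore-side grid ends
  peak <- max(det$sinogram$values)
  expect_lt(max(det$sinogram$values[, 1, ]), 1e-3 * peak)
  expect_lt(max(det$sinogram$values[, det$sinogram$geometry$n_channels, ]),
            1e-3 * peak)
})

test_that("cosine detruncation leaves untruncated scans value-unchanged", {
  g <- small_geometry()
  sino <- forward_project(disc_image(120, 0, matrix = 128), g)
  det <- cosine_detruncate(sino)
  blk <- efovct:::centered_block(det$sinogram$geometry$n_channels,
                                 g$n_channels)
  expect_identical(det$sinogram$values[, blk[1]:blk[2], ], sino$values[, , ])
  expect_equal(max(abs(det$sinogram$values[, -(blk[1]:blk[2]), ])), 0)
})

test_that("linear-cos^2 extension obeys its boundary conditions", {
  fx <- trunc_fixture(n_angles = 96)
  det <- linear_cos2_detruncate(fx$meas)
  ge <- det$sinogram$geometry
  blk <- efovct:::centered_block(ge$n_channels, fx$g$n_channels)
  du <- fx$g$channel_spacing_mm
  v <- det$sinogram$values[, , 1]
  p_edge <- fx$meas$values[, fx$g$n_channels, 1]
  slope <- (fx$meas$values[, fx$g$n_channels, 1] -
              fx$meas$values[, fx$g$n_channels - 1, 1]) / du
  a <- which.max(p_edge)                    # strongly truncated view
  # value continuity at the edge: first extension channel close to p_edge
  # (the cos^2 window reaches zero one spacing beyond the last channel)
  wbore <- (ge$n_channels - blk[2] + 1) * du
  expected_first <- max(0, p_edge[a] + slope[a] * du) *
    cos((pi / 2) * du / wbore)^2
  expect_equal(v[a, blk[2] + 1], expected_first, tolerance = 1e-7)
  # slope continuity: finite-difference slope of the extension ~ s
  fd <- (v[a, blk[2] + 1] - p_edge[a]) / du
  expect_lt(abs(fd - slope[a]), abs(slope[a]) * 0.1 + 0.05)
  # decayed to (near) zero at the bore end
  expect_lt(max(abs(v[, ge$n_channels])), 1e-2 * max(v))
  # rows without truncation at either edge stay zero outside
  quiet <- which(p_edge < 1e-9 & fx$meas$values[, 1, 1] < 1e-9)
  expect_equal(max(abs(v[quiet, -(blk[1]:blk[2])])), 0)
})

test_that("constant-edge rows degenerate to a pure cos^2 decay", {
  g <- small_geometry(n_angles = 8)
  v <- matrix(2, 8, g$n_channels)           # flat rows: slope 0 at edges
  sino <- sinogram(v, g)
  det <- linear_cos2_detruncate(sino)
  ge <- det$sinogram$geometry
  blk <- efovct:::centered_block(ge$n_channels, g$n_channels)
  d <- seq_len(ge$n_channels - blk[2]) * g$channel_spacing_mm
  wbore <- max(d) + g$channel_spacing_mm
  expect_equal(det$sinogram$values[1, (blk[2] + 1):ge$n_channels, 1],
               2 * cos((pi / 2) * d / wbore)^2, tolerance = 1e-12)
})

test_that("binarization recovers smooth object areas and couples slices", {
  img <- disc_image(100, 0, matrix = 128)
  mask <- binarize_object(img, sigma_mm = 5, sigma_slices = 0)
  area <- sum(mask$values) * mask$pixel_spacing_mm^2
  expect_lt(abs(area / (pi * 100^2) - 1), 0.03)

  # middle-slice object leaks into neighbours only with sigma_slices > 0
  stack <- ct_image(array(-1000, c(64, 64, 3)), 800 / 64)
  stack$values[20:44, 20:44, 2] <- 3000
  m0 <- binarize_object(stack, sigma_mm = 0, sigma_slices = 0)
  m1 <- binarize_object(stack, sigma_mm = 0, sigma_slices = 1)
  expect_equal(sum(m0$values[, , 1]), 0)
  expect_gt(sum(m1$values[, , 1]), 0)

  air <- ct_image(matrix(-1000, 32, 32), 25)
  expect_error(binarize_object(air), class = "efovct_empty_mask")
})

test_that("mask forward projection matches the water chord oracle", {
  g <- small_geometry()
  mask <- disc_mask(100, matrix = 128)
  sino <- mask_to_sinogram(mask, g)
  ge <- sino$geometry
  u <- channel_offsets(ge)
  t <- g$source_to_isocenter_mm * u /
    sqrt(g$source_to_detector_mm^2 + u^2)
  mid <- which.min(abs(u))
  expect_equal(sino$values[1, mid, 1], 2 * sqrt(100^2 - t[mid]^2) * 0.02,
               tolerance = 0.02)
  empty <- mask
  empty$values[] <- FALSE
  expect_equal(max(abs(mask_to_sinogram(empty, g)$values)), 0)
})

test_that("merging preserves measured data and feathers the junction", {
  fx <- trunc_fixture(n_angles = 96)
  ge <- extend_geometry(fx$g)
  sim <- forward_project(fx$ph$image, ge)    # simulated bore-wide data
  blk <- efovct:::centered_block(ge$n_channels, fx$g$n_channels)
  # simulated == measured on the overlap: merge equals simulated everywhere
  # (feathering is inert up to the one-channel discretization step)
  merged0 <- merge_sinograms(fx$meas, sim, feather = 0)
  expect_identical(merged0$values[, blk[1]:blk[2], ], fx$meas$values[, , ])
  expect_equal(merged0$values, sim$values, tolerance = 1e-12)
  merged <- merge_sinograms(fx$meas, sim)
  expect_identical(merged$values[, blk[1]:blk[2], ], fx$meas$values[, , ])
  expect_lt(max(abs(merged$values - sim$values)), 0.05 * max(sim$values))

  # zero simulated data with feathering disabled: zero-padded measured
  zero <- sim
  zero$values[] <- 0
  m0 <- merge_sinograms(fx$meas, zero, feather = 0)
  expect_equal(max(abs(m0$values[, -(blk[1]:blk[2]), ])), 0)
  expect_identical(m0$values[, blk[1]:blk[2], ], fx$meas$values[, , ])

  # feathering decays the junction jump on the simulated side only
  m3 <- merge_sinograms(fx$meas, zero, feather = 3)
  expect_identical(m3$values[, blk[1]:blk[2], ], fx$meas$values[, , ])
  a <- which.max(fx$meas$values[, fx$g$n_channels, 1])
  jump <- fx$meas$values[a, fx$g$n_channels, 1]
  expect_equal(m3$values[a, blk[2] + 1, 1], jump * 3 / 4, tolerance = 1e-9)
  expect_equal(m3$values[a, blk[2] + 4, 1], 0)

  g2 <- small_geometry(n_angles = 12)
  bad <- forward_project(disc_image(50, 0, matrix = 64), g2)
  expect_error(merge_sinograms(fx$meas, bad), "match")
})

test_that("HDFoV improves the eFoV contour over naive zero-padded FBP", {
  fx <- trunc_fixture()
  truth <- efovct:::analytic_mask(fx$ph$spec, 256, 800)
  naive <- fbp_reconstruct(fx$meas, fov_mm = 800, matrix = 256)
  hd <- hdfov_reconstruct(fx$meas, fov_mm = 800, matrix = 256)
  j_naive <- jaccard_efov(truth, object_mask(naive), fx$g)
  j_hd <- jaccard_efov(truth, object_mask(hd), fx$g)
  expect_gt(j_hd, j_naive)
  expect_gt(j_hd, 0.8)
})
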