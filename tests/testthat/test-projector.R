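test_that("air projects to zero and geometry coverage is enforced", {
  g <- small_geometry()
  img <- ct_image(matrix(-1000, 64, 64), 800 / 64)
  sino <- forward_project(img, g)
  expect_equal(max(abs(sino$values)), 0)
  g_bad <- g
  g_bad$n_channels <- 60L
  expect_error(forward_project(img, g_bad), "cover")
})

test_that("disc projections match the analytic chord oracle", {
  g <- small_geometry()
  r <- 120
  img <- disc_image(r, 0, matrix = 256)
  sino <- forward_project(img, g)
  u <- channel_offsets(g)
  rf <- g$source_to_isocenter_mm
  rfd <- g$source_to_detector_mm
  t <- rf * u / sqrt(rfd^2 + u^2)
  chord <- ifelse(abs(t) < r, 2 * sqrt(pmax(r^2 - t^2, 0)) * 0.02, 0)
  for (a in c(1, 25, 60)) {
    err <- sino$values[a, , 1] - chord
    expect_lt(max(abs(err)), 0.2)           # edge channels, discretization
    expect_lt(mean(abs(err)), 0.02)
  }
  # central channel of the fan sees the full diameter
  expect_equal(sino$values[1, 63, 1], 2 * r * 0.02, tolerance = 0.02)
})

test_that("forward projection is linear in the attenuation image", {
  g <- small_geometry(n_angles = 24)
  img1 <- disc_image(100, 200, matrix = 128)
  img2 <- disc_image(150, -300, matrix = 128, center = c(60, -40))
  mu1 <- hu_to_mu(img1)
  mu2 <- hu_to_mu(img2)
  comb <- mu1
  comb$values <- 2 * mu1$values + 0.5 * mu2$values
  s_comb <- forward_project(comb, g, values_are = "mu")
  s1 <- forward_project(mu1, g, values_are = "mu")
  s2 <- forward_project(mu2, g, values_are = "mu")
  expect_equal(s_comb$values, 2 * s1$values + 0.5 * s2$values,
               tolerance = 1e-12)
})

test_that("offset disc projections vary with angle but conserve mass", {
  g <- small_geometry()
  r <- 80
  img <- disc_image(r, 0, matrix = 256, center = c(100, 0))
  sino <- forward_project(img, g)
  mid <- (g$n_channels + 0) / 2
  central <- sino$values[, mid, 1]
  expect_gt(sd(central), 0.05)              # sinusoidal channel migration
  mp <- projection_mass(sino)
  area_mass <- pi * r^2 * 0.02
  expect_lt(max(abs(mp$mass / area_mass - 1)), 0.005)
})

test_that("truncation retains the central block bit-exactly", {
  g <- small_geometry(n_angles = 24)
  ge <- extend_geometry(g)
  img <- disc_image(300, 100, matrix = 128)   # wider than the sFoV
  wide <- forward_project(img, ge)
  trunc <- truncate_sinogram(wide, g)
  blk <- efovct:::centered_block(ge$n_channels, g$n_channels)
  expect_identical(trunc$values[, , 1], wide$values[, blk[1]:blk[2], 1])
  expect_true(all(trunc$measured_mask))
  # nonzero data are removed at the edges for this wide object
  removed <- wide$values[, -(blk[1]:blk[2]), 1]
  expect_gt(max(removed), 0.5)
  # a small object loses nothing
  small <- forward_project(disc_image(100, 0, matrix = 128), ge)
  expect_equal(max(abs(small$values[, -(blk[1]:blk[2]), 1])), 0)
})

test_that("sinogram construction validates its invariants", {
  g <- small_geometry(n_angles = 24)
  v <- matrix(1, 24, 126)
  expect_error(sinogram(matrix(1, 23, 126), g), "angle count")
  expect_error(sinogram(matrix(1, 24, 125), g), "channel count")
  mask <- rep(TRUE, 126)
  mask[60] <- FALSE                       # hole: not contiguous
  expect_error(sinogram(v, g, mask), "contiguous")
  v[1] <- Inf
  expect_error(sinogram(v, g), "non-finite")
})
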