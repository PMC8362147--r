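test_that("phantom specs reject components outside the bore", {
  expect_error(phantom_spec(data.frame(
    shape = "ellipse", cx = 200, cy = 0, ax = 250, ay = 100, rot = 0,
    hu = 0)), "bore")
  expect_silent(thorax_spec())
})

test_that("rasterized thorax matches its analytic geometry", {
  spec <- thorax_spec(n_slices = 1)
  ph <- make_thorax_phantom(spec)
  # analytic ellipse area oracle for the body mask
  area <- sum(ph$mask) * ph$image$pixel_spacing_mm^2
  expect_lt(abs(area / (pi * 280 * 135) - 1), 0.005)
  # the body exceeds the sFoV circle
  xs <- efovct:::image_axis(ph$image, 1)
  outside_sfov <- array(outer(xs^2, xs^2, `+`) > 250^2, dim(ph$mask))
  expect_gt(sum(ph$mask & outside_sfov), 0)
  # uniform body with no inserts: body HU histogram has lungs + bulk only
  hu_inside <- ph$image$values[ph$mask]
  expect_setequal(unique(hu_inside), c(100, -700))
  # rasterization agrees with the analytic test at 2 mm sampling
  m2 <- rasterize_phantom(spec, 400, 800, "mask")
  xs2 <- (seq_len(400) - 200.5) * 2
  analytic <- outer((xs2 / 280)^2, (xs2 / 135)^2, `+`) <= 1
  expect_gte(mean(m2[, , 1] == analytic), 0.995)
})

test_that("slice profile shrinks the outline towards the stack ends", {
  ph <- make_thorax_phantom(thorax_spec(n_slices = 5),
                            pixel_spacing_mm = 800 / 128)
  areas <- apply(ph$mask, 3, sum)
  expect_lt(areas[1], areas[3])
  expect_equal(areas[1], areas[5])
})

test_that("couch shifts are rigid and validated against the bore", {
  ph <- make_thorax_phantom(thorax_spec(n_slices = 1),
                            pixel_spacing_mm = 800 / 128)
  expect_identical(shift_couch(ph, 0)$image$values, ph$image$values)
  sh <- shift_couch(shift_couch(ph, 90), 30)
  expect_equal(sh$spec$shift, c(0, 120))
  expect_equal(sh$image$origin, c(0, 120))
  expect_equal(sum(sh$mask), sum(ph$mask))      # area invariant
  expect_error(shift_couch(ph, 300), "bore")
})

test_that("geometric distortion scales areas and fixes the output grid", {
  ph <- make_thorax_phantom(thorax_spec(width_mm = 400, height_mm = 200,
                                        n_slices = 1),
                            pixel_spacing_mm = 800 / 256)
  idn <- distort_image(ph$image, 1, 0, c(0, 0))
  expect_equal(idn$values, ph$image$values, tolerance = 1e-8)
  expect_equal(attr(idn, "transform")$scale, 1)

  sc <- distort_image(ph$image, 1.5, 0.3, c(20, -10))
  expect_equal(dim(sc$values)[1] * sc$pixel_spacing_mm, 800)
  # count at the half-way threshold so resampling blur cancels at edges
  a0 <- sum(ph$image$values > -450)
  a1 <- sum(sc$values > -450)
  expect_lt(abs(a1 / (1.5^2 * a0) - 1), 0.02)

  expect_error(distort_image(ph$image, 2.2, 0, c(0, 0)), "bore")
})

test_that("stitched reference recovers the wide phantom from two scans", {
  g <- scan_geometry(n_angles = 180)
  ph <- make_thorax_phantom(thorax_spec(n_slices = 1),
                            pixel_spacing_mm = 800 / 256)
  ref <- stitched_reference(ph, g, lateral_shift_mm = 60, matrix = 256)
  truth <- efovct:::analytic_mask(ph$spec, 256, 800)
  j <- jaccard_efov(truth, object_mask(ref), g)
  expect_gte(j, 0.99)
  # seam continuity: HU jump across the midline stays small in the body
  n <- dim(ref$values)[1]
  xs <- efovct:::image_axis(ref, 1)
  i_left <- max(which(xs < 0))
  interior <- abs(efovct:::image_axis(ref, 2)) < 100
  jumps <- abs(ref$values[i_left, interior, 1] -
                 ref$values[i_left + 1, interior, 1])
  expect_lt(max(jumps), 30)
  # shifting a half out of the sFoV is rejected
  expect_error(stitched_reference(shift_couch(ph, 120), g, 60,
                                  matrix = 256), "sFoV")
})
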