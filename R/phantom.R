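#' Declarative ellipse/circle phantom specification
#'
#' A phantom is an ordered list of components (later components overwrite
#' earlier ones where they overlap), each an ellipse or circle with an HU
#' value.  The first component is taken as the body outline: the analytic
#' ground-truth mask is its filled interior.  A per-slice scaling profile
#' shrinks the whole outline towards the superior/inferior ends to mimic a
#' smoothly varying body contour.
#'
#' @param components `data.frame` with columns `shape` ("ellipse" or
#'   "circle"), `cx`, `cy` (center, mm), `ax`, `ay` (semi-axes, mm; for a
#'   circle `ay` is ignored), `rot` (radians) and `hu`.
#' @param n_slices Number of slices.
#' @param slice_profile Numeric vector of per-slice scale factors (default:
#'   a shallow quadratic dome, 1 at the center, 0.93 at the ends).
#' @param slice_thickness_mm Slice thickness (mm).
#' @param bore_radius_mm Every component must fit inside this circle.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(components, n_slices = 1L, slice_profile = NULL,
                         slice_thickness_mm = 18, bore_radius_mm = 400) {
  stopifnot(is.data.frame(components),
            all(c("shape", "cx", "cy", "ax", "ay", "rot", "hu") %in%
                  names(components)))
  components$ay <- ifelse(components$shape == "circle", components$ax,
                          components$ay)
  if (is.null(slice_profile)) {
    if (n_slices == 1L) slice_profile <- 1
    else {
      z <- (seq_len(n_slices) - (n_slices + 1) / 2) / ((n_slices - 1) / 2)
      slice_profile <- 1 - 0.07 * z^2
    }
  }
  stopifnot(length(slice_profile) == n_slices, all(slice_profile > 0))
  spec <- list(components = components, n_slices = as.integer(n_slices),
               slice_profile = slice_profile,
               slice_thickness_mm = slice_thickness_mm,
               bore_radius_mm = bore_radius_mm, shift = c(0, 0))
  class(spec) <- "phantom_spec"
  check_inside_bore(spec)
  spec
}

check_inside_bore <- function(spec) {
  co <- spec$components
  reach <- sqrt((co$cx + spec$shift[1])^2 + (co$cy + spec$shift[2])^2) +
    pmax(co$ax, co$ay)
  if (any(reach > spec$bore_radius_mm))
    stop(sprintf("component %d extends to %.0f mm, beyond the %.0f mm bore",
                 which.max(reach), max(reach), spec$bore_radius_mm))
  invisible(spec)
}

#' Thorax-like phantom specification
#'
#' An elliptical body (default 560 mm x 270 mm, wider than the 500 mm
#' sFoV) of PLA-like bulk (about +100 HU) with two low-density lung
#' ellipses, and optionally a pair of tissue-mimicking circular inserts of
#' the chosen material: one at the top-left (eFoV when the couch is
#' raised) and one at the center (the sFoV reference position).
#'
#' @param width_mm,height_mm Body outer diameter along x and y.
#' @param body_hu,lung_hu Bulk and lung HU.
#' @param insert Optional material name from [insert_materials()].
#' @param insert_radius_mm Insert radius (mm).
#' @param n_slices,slice_thickness_mm Passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
thorax_spec <- function(width_mm = 560, height_mm = 270, body_hu = 100,
                        lung_hu = -700, insert = NULL,
                        insert_radius_mm = 15, n_slices = 1L,
                        slice_thickness_mm = 18) {
  a <- width_mm / 2
  b <- height_mm / 2
  comps <- data.frame(
    shape = c("ellipse", "ellipse", "ellipse"),
    cx = c(0, -0.41 * width_mm / 1.36, 0.41 * width_mm / 1.36),
    cy = c(0, 0, 0),
    ax = c(a, 0.30 * a, 0.30 * a),
    ay = c(b, 0.48 * b, 0.48 * b),
    rot = 0,
    hu = c(body_hu, lung_hu, lung_hu))
  if (!is.null(insert)) {
    hu <- insert_materials()[[insert]]
    if (is.null(hu)) stop("unknown insert material: ", insert)
    comps <- rbind(comps, data.frame(
      shape = "circle",
      cx = c(-0.71 * a, 0), cy = c(0.41 * b, 0),
      ax = insert_radius_mm, ay = insert_radius_mm, rot = 0, hu = hu))
  }
  phantom_spec(comps, n_slices = n_slices,
               slice_thickness_mm = slice_thickness_mm)
}

#' Nominal HU of the tissue-mimicking insert materials
#'
#' Configuration defaults (nominal tissue values), not measured ground
#' truth for any specific commercial insert set.
#'
#' @return Named list of HU values.
#' @export
insert_materials <- function() {
  list(breast = -35, muscle = 40, adipose = -90, solid_water = 0,
       cortical_bone = 1200, inner_bone = 220, liver = 60,
       inhale_lung = -800, exhale_lung = -500)
}

# analytic inside test for one scaled/shifted component on a pixel grid
component_inside <- function(comp, xs, ys, shift, scale) {
  cx <- comp$cx * scale + shift[1]
  cy <- comp$cy * scale + shift[2]
  ax <- comp$ax * scale
  ay <- comp$ay * scale
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  if (comp$rot != 0) {
    c0 <- cos(comp$rot); s0 <- sin(comp$rot)
    dxr <- c0 * dx + s0 * dy
    dy <- -s0 * dx + c0 * dy
    dx <- dxr
  }
  (dx / ax)^2 + (dy / ay)^2 <= 1
}

#' Rasterize a phantom specification
#'
#' Pixel-center sampling of the analytic component tests on an
#' isocenter-centered grid.
#'
#' @param spec A [phantom_spec()].
#' @param matrix Grid size.
#' @param fov_mm Physical grid extent (mm).
#' @param what `"hu"` for the HU image (air background -1000) or `"mask"`
#'   for the exact analytic body mask (first component, filled).
#' @return A [ct_image()] (HU) or a logical array (mask).
#' @export
rasterize_phantom <- function(spec, matrix = 512, fov_mm = 800,
                              what = c("hu", "mask")) {
  what <- match.arg(what)
  xs <- (seq_len(matrix) - (matrix + 1) / 2) * fov_mm / matrix
  ns <- spec$n_slices
  if (what == "mask") {
    out <- array(FALSE, c(matrix, matrix, ns))
    for (k in seq_len(ns))
      out[, , k] <- component_inside(spec$components[1, ], xs, xs,
                                     spec$shift, spec$slice_profile[k])
    return(out)
  }
  vals <- array(-1000, c(matrix, matrix, ns))
  for (k in seq_len(ns)) {
    sl <- array(-1000, c(matrix, matrix))
    for (i in seq_len(nrow(spec$components))) {
      ins <- component_inside(spec$components[i, ], xs, xs, spec$shift,
                              spec$slice_profile[k])
      sl[ins] <- spec$components$hu[i]
    }
    vals[, , k] <- sl
  }
  ct_image(vals, fov_mm / matrix, spec$slice_thickness_mm)
}

#' Build a phantom image stack with its analytic ground-truth mask
#'
#' @param spec A [phantom_spec()], e.g. [thorax_spec()].
#' @param pixel_spacing_mm In-plane voxel size; with the default 800 mm
#'   extent this fixes the matrix size (800/512 = 1.5625 mm by default).
#' @param fov_mm Physical grid extent.
#' @return A list of class `ct_phantom` with elements `image`
#'   ([ct_image()]), `mask` (logical array, analytic body outline) and
#'   `spec`.
#' @export
#' @examples
#' ph <- make_thorax_phantom(thorax_spec(n_slices = 1))
#' dim(ph$image$values)
make_thorax_phantom <- function(spec = thorax_spec(),
                                pixel_spacing_mm = 800 / 512,
                                fov_mm = 800) {
  matrix <- round(fov_mm / pixel_spacing_mm)
  img <- rasterize_phantom(spec, matrix, fov_mm, "hu")
  msk <- rasterize_phantom(spec, matrix, fov_mm, "mask")
  out <- list(image = img, mask = msk, spec = spec)
  class(out) <- "ct_phantom"
  out
}

#' Shift an object vertically (couch-height change)
#'
#' For a `ct_image` this only updates the grid origin (rigid bookkeeping
#' translation, no resampling unless `resample = TRUE`); for a
#' `ct_phantom` the specification, image origin and analytic mask move
#' together.  Shifts that push the phantom outside the bore are rejected.
#'
#' @param x A [ct_image()] or `ct_phantom`.
#' @param dy_mm Vertical shift (mm, positive = up).
#' @param resample If `TRUE`, resample the image onto the fixed original
#'   grid instead of moving the grid.
#' @return The shifted object.
#' @export
shift_couch <- function(x, dy_mm, resample = FALSE) {
  if (inherits(x, "ct_phantom")) {
    spec <- x$spec
    spec$shift <- spec$shift + c(0, dy_mm)
    check_inside_bore(spec)
    img <- shift_couch(x$image, dy_mm, resample)
    if (resample) {
      n <- dim(img$values)[1]
      msk <- rasterize_phantom(spec, n, n * img$pixel_spacing_mm, "mask")
    } else {
      msk <- x$mask
    }
    out <- list(image = img, mask = msk, spec = spec)
    class(out) <- "ct_phantom"
    return(out)
  }
  stopifnot(inherits(x, "ct_image"))
  if (resample) return(translate_image(x, 0, dy_mm))
  x$origin <- x$origin + c(0, dy_mm)
  x
}

#' Geometrically distort an image (scale, rotate, shift)
#'
#' Resamples the image onto an 800 mm x 800 mm output grid after an
#' affine transform (applied about the isocenter, in the order scale,
#' rotate, shift), as used to turn a body-like slice into a
#' ground-truth image that exceeds the sFoV while fitting the bore.  The
#' transform is recorded in the `transform` attribute.
#'
#' @param image A [ct_image()].
#' @param scale Isotropic scale factor.
#' @param rotation_rad Rotation (radians, counter-clockwise).
#' @param shift_mm Length-2 translation (mm).
#' @param bore_radius_mm The transformed body (non-air content) must lie
#'   inside this circle.
#' @param out_fov_mm,out_matrix Output grid (default 800 mm at the input
#'   matrix size).
#' @return A transformed `ct_image` centered at the isocenter.
#' @export
distort_image <- function(image, scale = 1, rotation_rad = 0,
                          shift_mm = c(0, 0), bore_radius_mm = 400,
                          out_fov_mm = 800, out_matrix = NULL) {
  stopifnot(scale > 0)
  if (is.null(out_matrix)) out_matrix <- dim(image$values)[1]
  sp_out <- out_fov_mm / out_matrix
  xo <- (seq_len(out_matrix) - (out_matrix + 1) / 2) * sp_out
  xs <- image_axis(image, 1)
  ys <- image_axis(image, 2)
  c0 <- cos(-rotation_rad); s0 <- sin(-rotation_rad)
  ns <- n_slices(image)
  vals <- array(-1000, c(out_matrix, out_matrix, ns))
  # inverse map: q = R(-theta) (p - shift) / scale, separable per output row
  for (k in seq_len(ns)) {
    for (j in seq_len(out_matrix)) {
      px <- xo - shift_mm[1]
      py <- xo[j] - shift_mm[2]
      qx <- (c0 * px - s0 * py) / scale
      qy <- (s0 * px + c0 * py) / scale
      vals[, j, k] <- bilinear_interp_points(image$values[, , k], xs, ys,
                                             qx, qy, -1000)
    }
  }
  out <- ct_image(vals, sp_out, image$slice_thickness_mm)
  body <- which(out$values[, , 1] > -900, arr.ind = TRUE)
  if (length(body)) {
    r <- sqrt(xo[body[, 1]]^2 + xo[body[, 2]]^2)
    if (max(r) > bore_radius_mm)
      stop(sprintf("transformed body reaches %.0f mm, beyond the %.0f mm bore",
                   max(r), bore_radius_mm))
  }
  attr(out, "transform") <- list(scale = scale, rotation_rad = rotation_rad,
                                 shift_mm = shift_mm)
  out
}

# bilinear sample of `slice` (on xs x ys grid) at paired points (qx, qy)
bilinear_interp_points <- function(slice, xs, ys, qx, qy, fill = -1000) {
  nx <- length(xs)
  dx <- xs[2] - xs[1]
  fx <- (qx - xs[1]) / dx
  fy <- (qy - ys[1]) / dx
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  val <- function(i, j) {
    ok <- i >= 0 & i < nx & j >= 0 & j < nx
    v <- rep(fill, length(i))
    v[ok] <- slice[cbind(i[ok] + 1L, j[ok] + 1L)]
    v
  }
  (1 - wx) * (1 - wy) * val(i0, j0) + wx * (1 - wy) * val(i0 + 1, j0) +
    (1 - wx) * wy * val(i0, j0 + 1) + wx * wy * val(i0 + 1, j0 + 1)
}

#' Stitched two-scan reference reconstruction
#'
#' Emulates the reference protocol for objects wider than the sFoV: the
#' phantom is scanned twice, shifted laterally so that each half lies
#' inside the sFoV, each scan is reconstructed, shifted back, and the two
#' halves are joined with a hard seam at the phantom midline.  The result
#' consists only of measured (untruncated) data and serves as the
#' reference image for the quantitative metrics.
#'
#' @param phantom A `ct_phantom` (couch at the height at which the
#'   reference is acquired; each half after the lateral shift must fit in
#'   the sFoV).
#' @param geometry Physical [scan_geometry()].
#' @param lateral_shift_mm Magnitude of the left/right shift (mm).
#' @param fov_mm,matrix,filter Reconstruction settings.
#' @return A [ct_image()] reference reconstruction.
#' @export
stitched_reference <- function(phantom, geometry, lateral_shift_mm = 60,
                               fov_mm = 800, matrix = 512,
                               filter = "ramlak") {
  stopifnot(inherits(phantom, "ct_phantom"))
  halves <- vector("list", 2L)
  for (side in 1:2) {
    s <- if (side == 1) lateral_shift_mm else -lateral_shift_mm
    spec <- phantom$spec
    spec$shift <- spec$shift + c(s, 0)
    # the half moved toward the center must lie inside the sFoV
    n <- dim(phantom$image$values)[1]
    msk <- rasterize_phantom(spec, n, n * phantom$image$pixel_spacing_mm,
                             "mask")
    xs <- (seq_len(n) - (n + 1) / 2) * phantom$image$pixel_spacing_mm
    keep_half <- if (side == 1) xs - phantom$spec$shift[1] - s <= 0 else
      xs - phantom$spec$shift[1] - s >= 0
    half <- msk & array(keep_half, dim(msk))
    r2 <- outer(xs^2, xs^2, `+`)
    if (any(half & array(r2 > geometry$sfov_radius_mm^2, dim(half))))
      stop("phantom half does not fit inside the sFoV after the shift")
    img <- phantom$image
    img$origin <- img$origin + c(s, 0)
    sino <- truncate_sinogram(
      forward_project(img, extend_geometry(geometry)), geometry)
    rec <- fbp_reconstruct(sino, fov_mm = fov_mm, matrix = matrix,
                           filter = filter)
    halves[[side]] <- translate_image(rec, -s, 0)
  }
  out <- halves[[1]]
  xs <- image_axis(out, 1)
  right <- xs - phantom$spec$shift[1] > 0
  out$values[right, , ] <- halves[[2]]$values[right, , ]
  out
}
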