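#' CT image stack on a physical grid
#'
#' A stack of square in-plane slices with Hounsfield-unit (HU) values.  The
#' grid is centered at `origin` (mm, relative to the scanner isocenter);
#' voxel (i, j) of a slice sits at
#' `origin + ((i, j) - (n + 1)/2) * pixel_spacing_mm`, with the first index
#' running along x (horizontal, couch-lateral) and the second along y
#' (vertical, couch height).
#'
#' @param values Numeric array `n x n x n_slices` (a matrix is treated as a
#'   single slice) of HU values; clipped below at -1000 (air).
#' @param pixel_spacing_mm In-plane voxel size (mm).
#' @param slice_thickness_mm Slice thickness (mm).
#' @param origin Length-2 numeric, grid-center offset from isocenter (mm).
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(values, pixel_spacing_mm, slice_thickness_mm = 3,
                     origin = c(0, 0)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, dim(values)[1] == dim(values)[2])
  if (any(!is.finite(values))) stop("non-finite HU values")
  values[values < -1000] <- -1000
  img <- list(values = values,
              pixel_spacing_mm = pixel_spacing_mm,
              slice_thickness_mm = slice_thickness_mm,
              origin = as.numeric(origin))
  class(img) <- "ct_image"
  img
}

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ct_image> %d x %d x %d slices, %.4g mm pixels, origin (%.1f, %.1f) mm\n",
    d[1], d[2], d[3], x$pixel_spacing_mm, x$origin[1], x$origin[2]))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$values), max(x$values)))
  invisible(x)
}

n_slices <- function(image) dim(image$values)[3]

# physical x (or y) coordinates of voxel centers
image_axis <- function(image, axis = 1L) {
  n <- dim(image$values)[1]
  (seq_len(n) - (n + 1) / 2) * image$pixel_spacing_mm + image$origin[axis]
}

#' Convert HU to linear attenuation
#'
#' `mu = mu_water_per_mm * (1 + HU/1000)`, clipped at 0.  The inverse
#' [mu_to_hu()] satisfies the round-trip identity for HU >= -1000.
#'
#' @param image A [ct_image()] in HU.
#' @param mu_water_per_mm Linear attenuation of water (1/mm); default 0.02,
#'   roughly a 70 keV effective energy.
#' @return A `ct_image`-shaped object whose values are attenuation (1/mm).
#' @export
#' @examples
#' img <- ct_image(matrix(0, 8, 8), 1)
#' range(hu_to_mu(img)$values)   # water: 0.02 everywhere
hu_to_mu <- function(image, mu_water_per_mm = 0.02) {
  stopifnot(mu_water_per_mm > 0)
  if (any(!is.finite(image$values))) stop("non-finite HU values")
  out <- image
  out$values <- pmax(mu_water_per_mm * (1 + image$values / 1000), 0)
  out$unit <- "mu_per_mm"
  out
}

#' Convert linear attenuation to HU
#'
#' @param image A `ct_image` holding attenuation values (1/mm).
#' @inheritParams hu_to_mu
#' @return A `ct_image` in HU (floor -1000).
#' @export
mu_to_hu <- function(image, mu_water_per_mm = 0.02) {
  stopifnot(mu_water_per_mm > 0)
  out <- image
  out$values <- pmax(1000 * (image$values / mu_water_per_mm - 1), -1000)
  out$unit <- NULL
  out
}

#' Downsample an image by integer-factor area averaging
#'
#' @param image A [ct_image()].
#' @param out_size Target in-plane matrix size; must divide the input size.
#' @return The downsampled `ct_image` (same physical extent).
#' @export
downsample_image <- function(image, out_size) {
  n <- dim(image$values)[1]
  if (n %% out_size != 0) stop("out_size must divide the matrix size")
  f <- n %/% out_size
  ns <- n_slices(image)
  vals <- array(0, c(out_size, out_size, ns))
  idx <- rep(seq_len(out_size), each = f)
  for (k in seq_len(ns)) {
    m <- rowsum(image$values[, , k], idx)             # sum over row blocks
    vals[, , k] <- t(rowsum(t(m), idx)) / f^2
  }
  ct_image(vals, image$pixel_spacing_mm * f, image$slice_thickness_mm,
           image$origin)
}

#' Translate an image by resampling
#'
#' Bilinear resampling of every slice onto the same grid shifted by
#' `(dx, dy)` mm; voxels sampled from outside the input grid become air
#' (-1000 HU).  For pure bookkeeping shifts (no resampling) update `origin`
#' via [shift_couch()] instead.
#'
#' @param image A [ct_image()].
#' @param dx_mm,dy_mm Translation applied to the image content (mm).
#' @param fill Fill value for samples outside the grid.
#' @return A translated `ct_image` on the original grid.
#' @export
translate_image <- function(image, dx_mm, dy_mm, fill = -1000) {
  n <- dim(image$values)[1]
  sp <- image$pixel_spacing_mm
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  out <- image
  for (k in seq_len(n_slices(image)))
    out$values[, , k] <- bilinear_grid(image$values[, , k], xs, xs,
                                       xs - dx_mm, xs - dy_mm, fill)
  out
}

# sample slice (values on xs x ys grid) at outer product of xq, yq
bilinear_grid <- function(slice, xs, ys, xq, yq, fill = -1000) {
  nx <- length(xs)
  dx <- xs[2] - xs[1]
  fx <- (xq - xs[1]) / dx
  fy <- (yq - ys[1]) / dx
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  get <- function(i, j) {
    ok <- outer(i >= 0 & i < nx, j >= 0 & j < nx, `&`)
    ii <- pmax(pmin(i, nx - 1), 0) + 1
    jj <- pmax(pmin(j, nx - 1), 0) + 1
    v <- slice[ii, jj, drop = FALSE]
    v[!ok] <- fill
    v
  }
  wxm <- matrix(wx, length(xq), length(yq))
  wym <- matrix(wy, length(xq), length(yq), byrow = TRUE)
  (1 - wxm) * (1 - wym) * get(i0, j0) + wxm * (1 - wym) * get(i0 + 1, j0) +
    (1 - wxm) * wym * get(i0, j0 + 1) + wxm * wym * get(i0 + 1, j0 + 1)
}
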