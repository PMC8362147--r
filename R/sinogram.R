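#' Fan-beam sinogram
#'
#' Projection data (line integrals of linear attenuation, dimensionless) on
#' an `n_angles x n_channels x n_slices` array together with its
#' [scan_geometry()] and a per-channel `measured_mask` flagging the
#' contiguous central block of channels that was actually measured (as
#' opposed to extrapolated or simulated).
#'
#' @param values Array `n_angles x n_channels x n_slices` (a matrix is a
#'   single slice) of line integrals; must be finite.
#' @param geometry The [scan_geometry()] the data were acquired with (its
#'   `n_channels` must match `ncol(values)`).
#' @param measured_mask Logical vector per channel; default all `TRUE`.
#'   Must mark one contiguous block.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, measured_mask = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  if (any(!is.finite(values))) stop("non-finite sinogram values")
  if (dim(values)[1] != geometry$n_angles)
    stop("values/geometry angle count mismatch")
  if (dim(values)[2] != geometry$n_channels)
    stop("values/geometry channel count mismatch")
  if (is.null(measured_mask)) measured_mask <- rep(TRUE, geometry$n_channels)
  stopifnot(length(measured_mask) == geometry$n_channels)
  r <- rle(measured_mask)
  if (sum(r$values) != 1L)
    stop("measured_mask must be a single contiguous block")
  s <- list(values = values, geometry = geometry,
            measured_mask = measured_mask)
  class(s) <- "sinogram"
  s
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<sinogram> %d angles x %d channels x %d slices (%d measured channels)\n",
    d[1], d[2], d[3], sum(x$measured_mask)))
  invisible(x)
}

measured_range <- function(sino) range(which(sino$measured_mask))

#' Truncate a sinogram to the physical detector
#'
#' Removes channels beyond the physical detector of `geometry` from a wider
#' simulated sinogram; retained values are unchanged bit-exactly and all
#' remaining channels are flagged measured.
#'
#' @param sino A [sinogram()] on an extended (e.g. bore-covering) detector.
#' @param geometry The physical [scan_geometry()] to truncate to; must have
#'   the same spacing and at most as many channels.
#' @return A `sinogram` with `geometry$n_channels` channels.
#' @export
truncate_sinogram <- function(sino, geometry) {
  ge <- sino$geometry
  if (!isTRUE(all.equal(ge$channel_spacing_mm, geometry$channel_spacing_mm)))
    stop("channel spacing mismatch")
  if (geometry$n_channels > ge$n_channels)
    stop("target detector wider than source")
  blk <- centered_block(ge$n_channels, geometry$n_channels)
  sinogram(sino$values[, blk[1]:blk[2], , drop = FALSE], geometry)
}
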