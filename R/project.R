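#' Fan-beam forward projection
#'
#' Computes, per slice, the line integral of the linear attenuation along
#' the ray from the source through each detector channel center, by
#' fixed-step sampling (default step: half the image pixel spacing) with
#' bilinear interpolation.  Rays missing the image grid yield 0.  All
#' channels of the result are flagged measured; use [truncate_sinogram()]
#' to emulate the physical detector.
#'
#' @param image A [ct_image()]; interpreted per `values_are` either as HU
#'   (converted internally with `mu_water_per_mm`) or as attenuation.
#' @param geometry A [scan_geometry()] whose detector covers the sFoV.
#' @param values_are `"hu"` (default) or `"mu"`.
#' @param mu_water_per_mm Water attenuation used for the HU conversion.
#' @param step_mm Ray sampling step; default `pixel_spacing_mm / 2`.
#' @param clip_radius_mm Rays are integrated only inside a circle of this
#'   radius around the isocenter (default: slightly beyond the bore, the
#'   outer limit of any physical object); set `Inf` to integrate across
#'   the whole grid.
#' @return A [sinogram()] with `geometry$n_angles x geometry$n_channels`
#'   values per slice.
#' @export
#' @examples
#' g <- scan_geometry(n_angles = 90)
#' img <- ct_image(matrix(-1000, 64, 64), 800 / 64)
#' max(forward_project(img, g)$values)   # air scans to zero
forward_project <- function(image, geometry, values_are = c("hu", "mu"),
                            mu_water_per_mm = 0.02, step_mm = NULL,
                            clip_radius_mm = NULL) {
  values_are <- match.arg(values_are)
  if (is.null(clip_radius_mm))
    clip_radius_mm <- geometry$bore_radius_mm + 2 * image$pixel_spacing_mm
  if (!is.finite(clip_radius_mm)) clip_radius_mm <- -1
  hw <- geometry$n_channels * geometry$channel_spacing_mm / 2
  if (asin(geometry$sfov_radius_mm / geometry$source_to_isocenter_mm) >
      atan(hw / geometry$source_to_detector_mm))
    stop("detector does not cover the sFoV")
  mu <- if (values_are == "hu") hu_to_mu(image, mu_water_per_mm) else image
  if (is.null(step_mm)) step_mm <- image$pixel_spacing_mm / 2
  n <- dim(mu$values)[1]
  x0 <- image$origin[1] - (n - 1) / 2 * image$pixel_spacing_mm
  y0 <- image$origin[2] - (n - 1) / 2 * image$pixel_spacing_mm
  uoff <- channel_offsets(geometry)
  ns <- n_slices(image)
  vals <- array(0, c(geometry$n_angles, geometry$n_channels, ns))
  for (k in seq_len(ns))
    vals[, , k] <- .fp_slice(mu$values[, , k], x0, y0,
                             image$pixel_spacing_mm, geometry$angles_rad,
                             uoff, geometry$source_to_isocenter_mm,
                             geometry$source_to_detector_mm, step_mm,
                             clip_radius_mm)
  sinogram(vals, geometry)
}
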