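#' Fan-beam scan geometry
#'
#' Describes a single-slice fan-beam acquisition with a flat, equally spaced
#' detector: source-to-isocenter distance `RF`, source-to-detector distance
#' `RFD`, the channel grid, the projection angles (evenly spaced over a full
#' rotation), and the scanner's scan field of view (sFoV) and bore radii.
#' Channel centers sit at `(i - (n_channels - 1)/2) * channel_spacing_mm`
#' along the detector tangent.
#'
#' The defaults mimic a clinical scanner with `RF` = 595 mm, `RFD` =
#' 1086 mm, an sFoV of 500 mm diameter and an 800 mm bore.  The detector
#' must cover the sFoV: `asin(sfov_radius/RF) <= atan(half_width/RFD)` with
#' `half_width = n_channels * channel_spacing_mm / 2`.
#'
#' @param source_to_isocenter_mm Focus-to-isocenter distance RF (mm).
#' @param source_to_detector_mm Focus-to-detector distance RFD (mm).
#' @param n_channels Number of detector channels.
#' @param channel_spacing_mm Channel pitch at the detector (mm).
#' @param n_angles Number of projection angles over a full rotation.
#' @param sfov_radius_mm Scan field-of-view radius (mm).
#' @param bore_radius_mm Bore radius (mm); outer limit of any object.
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' g <- scan_geometry()
#' g$n_channels
scan_geometry <- function(source_to_isocenter_mm = 595,
                          source_to_detector_mm = 1086,
                          n_channels = 504,
                          channel_spacing_mm = 2,
                          n_angles = 720,
                          sfov_radius_mm = 250,
                          bore_radius_mm = 400) {
  stopifnot(source_to_isocenter_mm > 0, source_to_detector_mm > 0)
  if (source_to_isocenter_mm >= source_to_detector_mm)
    stop("RF must be smaller than RFD")
  if (sfov_radius_mm > bore_radius_mm)
    stop("sfov_radius_mm must not exceed bore_radius_mm")
  if (sfov_radius_mm >= source_to_isocenter_mm)
    stop("sFoV radius must be smaller than RF")
  half_width <- n_channels * channel_spacing_mm / 2
  if (asin(sfov_radius_mm / source_to_isocenter_mm) >
      atan(half_width / source_to_detector_mm))
    stop("detector half-width does not cover the sFoV circle")
  g <- list(
    source_to_isocenter_mm = source_to_isocenter_mm,
    source_to_detector_mm = source_to_detector_mm,
    n_channels = as.integer(n_channels),
    channel_spacing_mm = channel_spacing_mm,
    n_angles = as.integer(n_angles),
    angles_rad = seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)],
    sfov_radius_mm = sfov_radius_mm,
    bore_radius_mm = bore_radius_mm
  )
  class(g) <- "scan_geometry"
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> RF %.0f mm, RFD %.0f mm, %d channels x %.2f mm, %d angles\n",
    x$source_to_isocenter_mm, x$source_to_detector_mm, x$n_channels,
    x$channel_spacing_mm, x$n_angles))
  cat(sprintf("  sFoV radius %.0f mm, bore radius %.0f mm\n",
              x$sfov_radius_mm, x$bore_radius_mm))
  invisible(x)
}

#' Detector channel offsets
#'
#' Physical positions of channel centers along the detector tangent (mm).
#'
#' @param geometry A [scan_geometry()].
#' @return Numeric vector of length `n_channels`.
#' @export
channel_offsets <- function(geometry) {
  n <- geometry$n_channels
  (seq_len(n) - 1 - (n - 1) / 2) * geometry$channel_spacing_mm
}

# Detector half-width (mm) needed to cover a circle of the given radius
# around the isocenter.
detector_halfwidth_for_radius <- function(geometry, radius_mm) {
  rf <- geometry$source_to_isocenter_mm
  rfd <- geometry$source_to_detector_mm
  if (radius_mm >= rf) stop("radius must be smaller than RF")
  rfd * tan(asin(radius_mm / rf))
}

#' Extend a geometry's detector to cover a wider circle
#'
#' Returns a geometry identical to `geometry` but with a symmetric detector
#' wide enough to cover the circle of `radius_mm` (default: the bore).  Used
#' to simulate untruncated acquisitions and to build the extended channel
#' grid that detruncation writes into.
#'
#' @param geometry A [scan_geometry()].
#' @param radius_mm Radius to cover (mm); default `bore_radius_mm`.
#' @return A `scan_geometry` with more channels, same spacing and angles.
#' @export
extend_geometry <- function(geometry, radius_mm = geometry$bore_radius_mm) {
  hw <- detector_halfwidth_for_radius(geometry, radius_mm)
  nhalf <- ceiling(hw / geometry$channel_spacing_mm)
  n <- max(2L * as.integer(nhalf), geometry$n_channels)
  if ((n - geometry$n_channels) %% 2L != 0L) n <- n + 1L
  g <- geometry
  g$n_channels <- as.integer(n)
  g
}

# Parallel-equivalent weight dt/du for flat-detector fan rays: the fan ray at
# detector offset u corresponds to the parallel ray at signed distance
# t = RF * u / sqrt(RFD^2 + u^2); dt/du makes channel sums equal to parallel
# line-integral masses, which are angle-invariant for untruncated data.
fan_parallel_weight <- function(geometry, u) {
  rf <- geometry$source_to_isocenter_mm
  rfd <- geometry$source_to_detector_mm
  rf * rfd^2 / (rfd^2 + u^2)^1.5
}

# index range (1-based) of a centred block of n_inner channels inside a
# wider grid of n_outer channels (both even or both odd by construction)
centered_block <- function(n_outer, n_inner) {
  off <- (n_outer - n_inner) %/% 2L
  c(off + 1L, off + n_inner)
}
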