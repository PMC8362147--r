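#' Object mask of a reconstructed image
#'
#' Thresholding followed by largest-connected-component selection and
#' hole filling, per slice; the mask equals 1 on the object (phantom
#' area) and 0 elsewhere (air, and any region removed by the exclusion
#' predicate, e.g. a patient table — a no-op on table-free synthetic
#' data).
#'
#' @param image A [ct_image()] in HU.
#' @param threshold_hu Threshold (HU).
#' @param exclude Optional predicate `function(x, y)` (mm, isocenter
#'   frame) returning `TRUE` for pixels to force to background.
#' @return A `ct_mask`.  Signals `efovct_empty_mask` if nothing exceeds
#'   the threshold.
#' @export
object_mask <- function(image, threshold_hu = -400, exclude = NULL) {
  bin <- image$values > threshold_hu
  if (!is.null(exclude)) {
    xs <- image_axis(image, 1)
    ys <- image_axis(image, 2)
    ex <- outer(xs, ys, exclude)
    bin <- bin & !array(ex, dim(bin))
  }
  if (!any(bin))
    stop(structure(list(message = "no voxel above threshold",
                        call = sys.call()),
                   class = c("efovct_empty_mask", "error", "condition")))
  for (k in seq_len(dim(bin)[3]))
    bin[, , k] <- largest_component_filled(bin[, , k])
  mask <- list(values = bin, pixel_spacing_mm = image$pixel_spacing_mm,
               slice_thickness_mm = image$slice_thickness_mm,
               origin = image$origin)
  class(mask) <- c("ct_mask", "ct_image")
  mask
}

# logical array of pixels outside the sFoV circle, on the mask's grid
efov_region <- function(mask, geometry) {
  xs <- image_axis(mask, 1)
  ys <- image_axis(mask, 2)
  outer(xs^2, ys^2, `+`) > geometry$sfov_radius_mm^2
}

#' eFoV-restricted Jaccard Conformity Index
#'
#' Both masks are intersected with the eFoV region (pixels farther from
#' the isocenter than the sFoV radius) before computing
#' `|intersection| / |union|`: 1 for a perfect match, 0 for disjoint
#' regions.  If both masks are empty inside the eFoV the index is
#' defined as 1 and the result carries the attribute `empty_union =
#' TRUE`.
#'
#' @param mask_ref,mask_test `ct_mask` objects on identical grids.
#' @param geometry A [scan_geometry()] supplying the sFoV radius.
#' @return The Jaccard index in \[0, 1\] (one value over the full
#'   stack).
#' @export
jaccard_efov <- function(mask_ref, mask_test, geometry) {
  if (!identical(dim(mask_ref$values), dim(mask_test$values)) ||
      !isTRUE(all.equal(mask_ref$pixel_spacing_mm,
                        mask_test$pixel_spacing_mm)) ||
      !isTRUE(all.equal(mask_ref$origin, mask_test$origin)))
    stop("mask grids do not match")
  ef <- array(efov_region(mask_ref, geometry), dim(mask_ref$values))
  a <- mask_ref$values & ef
  b <- mask_test$values & ef
  uni <- sum(a | b)
  if (uni == 0) return(structure(1, empty_union = TRUE))
  sum(a & b) / uni
}

#' Per-slice eFoV volume of a mask
#'
#' Counts mask voxels outside the sFoV circle per slice and converts to
#' cm^3 with the voxel volume.
#'
#' @param mask A `ct_mask`.
#' @param geometry A [scan_geometry()].
#' @return Numeric vector (cm^3), one value per slice.
#' @export
slice_efov_volume <- function(mask, geometry) {
  ef <- efov_region(mask, geometry)
  vox_cm3 <- mask$pixel_spacing_mm^2 * mask$slice_thickness_mm / 1000
  vapply(seq_len(dim(mask$values)[3]),
         function(k) sum(mask$values[, , k] & ef) * vox_cm3, 0)
}

#' Root-mean-square deviation between two volume sequences
#'
#' @param ref,test Equal-length numeric vectors (cm^3).
#' @return `sqrt(mean((ref - test)^2))`.
#' @export
volume_rmsd <- function(ref, test) {
  if (length(ref) != length(test)) stop("length mismatch")
  sqrt(mean((ref - test)^2))
}

#' HU statistics in a cylindrical region of interest
#'
#' Mean and standard deviation over voxels within `radius_mm` of the ROI
#' center (axial view), across `n_slices` consecutive slices centered on
#' `center_slice` (defaults: 1 cm radius, 5 slices — the insert
#' evaluation protocol).
#'
#' @param image A [ct_image()].
#' @param center_mm Length-2 in-plane ROI center (mm, isocenter frame).
#' @param radius_mm ROI radius (mm).
#' @param n_slices Number of consecutive slices.
#' @param center_slice Central slice index (default: middle of the
#'   stack).
#' @return List with `mean`, `sd` and `n_voxels`.
#' @export
roi_hu_stats <- function(image, center_mm, radius_mm = 10, n_slices = 5,
                         center_slice = NULL) {
  nsl <- dim(image$values)[3]
  if (is.null(center_slice)) center_slice <- (nsl + 1L) %/% 2L
  k0 <- center_slice - (n_slices - 1L) %/% 2L
  ks <- k0:(k0 + n_slices - 1L)
  if (min(ks) < 1L || max(ks) > nsl)
    stop("ROI slice range outside the image stack")
  xs <- image_axis(image, 1)
  ys <- image_axis(image, 2)
  inroi <- outer((xs - center_mm[1])^2, (ys - center_mm[2])^2, `+`) <=
    radius_mm^2
  if (!any(inroi)) stop("ROI outside the image grid")
  if (min(xs) > center_mm[1] - radius_mm ||
      max(xs) < center_mm[1] + radius_mm ||
      min(ys) > center_mm[2] - radius_mm ||
      max(ys) < center_mm[2] + radius_mm)
    stop("ROI extends outside the image grid")
  v <- as.vector(apply(image$values[, , ks, drop = FALSE], 3,
                       function(sl) sl[inroi]))
  list(mean = mean(v), sd = stats::sd(v), n_voxels = length(v))
}

#' HU histogram over the eFoV part of a mask
#'
#' Histogram of HU values over `mask` intersected with the eFoV region,
#' on fixed bin edges anchored at multiples of `bin_width_hu` (so a
#' uniform HU shift of the image shifts the occupied bins by the same
#' amount).
#'
#' @param image A [ct_image()].
#' @param mask A `ct_mask` on the same grid.
#' @param geometry A [scan_geometry()].
#' @param bin_width_hu Bin width (HU).
#' @return List with `breaks`, `counts`, `density`, `n`.
#' @export
efov_hu_histogram <- function(image, mask, geometry, bin_width_hu = 10) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("image/mask grid mismatch")
  ef <- array(efov_region(mask, geometry), dim(mask$values))
  sel <- mask$values & ef
  if (!any(sel))
    stop(structure(list(message = "empty eFoV region", call = sys.call()),
                   class = c("efovct_empty_region", "error", "condition")))
  v <- image$values[sel]
  lo <- floor(min(v) / bin_width_hu) * bin_width_hu
  hi <- ceiling(max(v) / bin_width_hu) * bin_width_hu
  if (hi <= lo) hi <- lo + bin_width_hu
  breaks <- seq(lo, hi, by = bin_width_hu)
  counts <- as.vector(table(cut(v, breaks, include.lowest = TRUE,
                                right = FALSE)))
  list(breaks = breaks, counts = counts,
       density = counts / sum(counts) / bin_width_hu, n = length(v))
}
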