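#' Per-angle projection mass
#'
#' Projection mass in the parallel-equivalent measure: each fan ray
#' `(beta, u)` is rebinned to its parallel view (`theta = beta -
#' atan(u/RFD)`, offset `t = RF * sin(atan(u/RFD))`, i.e. fan rays
#' weighted by the rebinning Jacobian onto a uniform `t` grid), and the
#' mass of a view is `sum_t p(theta, t) * dt`.  For untruncated data the
#' parallel rows are true object projections, so this mass equals the
#' attenuation area integral at every view (up to interpolation error,
#' well below 0.5%); a raw per-fan-angle channel sum has no such
#' invariance at large fan angles.  The reference mass is the maximum
#' over views (truncation only removes mass) and the normalized profile
#' is `mass/reference`; truncated scans drop below 1 on the views that
#' lost rays.
#'
#' @param sino A [sinogram()]; channels beyond its grid count as zero
#'   (truncated data).
#' @return An object of class `mass_profile`: list with `mass`
#'   (`n_angles x n_slices`, one row per view), `reference` (per slice)
#'   and `normalized`.
#' @export
projection_mass <- function(sino) {
  g <- sino$geometry
  gext <- extend_geometry(g)
  tg <- parallel_grid(gext)
  nsl <- dim(sino$values)[3]
  blk <- centered_block(gext$n_channels, g$n_channels)
  mass <- matrix(0, g$n_angles, nsl)
  for (k in seq_len(nsl)) {
    vz <- matrix(0, g$n_angles, gext$n_channels)
    vz[, blk[1]:blk[2]] <- sino$values[, , k]
    mass[, k] <- rowSums(rebin_fan_to_parallel(vz, gext, tg)) * tg$dt
  }
  reference <- apply(mass, 2, max)
  if (any(reference <= 0))
    stop("all-zero sinogram: projection mass reference undefined")
  out <- list(mass = mass, reference = reference,
              normalized = sweep(mass, 2, reference, "/"))
  class(out) <- "mass_profile"
  out
}

# distances (mm) of the extension channels beyond each edge of the measured
# block, on the extended grid; list(left =, right =), nearest first
extension_distances <- function(n_ext, blk, du) {
  list(left = seq_len(blk[1] - 1L) * du,
       right = seq_len(n_ext - blk[2]) * du)
}

#' Mass-consistency cosine detruncation
#'
#' Restores per-view mass consistency: in the parallel-equivalent domain
#' (see [projection_mass()]) each truncated view is extended beyond the
#' measured detector with a cosine-squared lobe
#' `p(t_edge + d) = p_edge * cos^2((pi/2) d / W)` whose width `W` is
#' solved per view (bisection) so that the added mass equals that view's
#' deficit relative to the reference (maximum) mass, the deficit being
#' split between the two edges in proportion to the edge values.  If even
#' the full bore-wide width cannot absorb a deficit, the lobe amplitude
#' is boosted by a recorded correction factor.  The parallel-domain
#' extension is then resampled onto the fan sinogram's bore-wide
#' extension channels, and the lobe amplitudes are iteratively rescaled
#' until the mass profile of the resulting fan sinogram is flat to
#' `mass_tol`.  Measured channels are returned bit-exactly.
#'
#' @param sino A [sinogram()] (untruncated input is allowed and returned
#'   value-unchanged on its extended grid).
#' @param mass_tol Relative tolerance on the per-view normalized mass
#'   after detruncation.
#' @param max_iter Maximum amplitude-correction iterations.
#' @return An object of class `detruncation_result`: list with `sinogram`
#'   (bore-wide grid, `measured_mask` marking the input block),
#'   `added_mass` (`n_angles x n_slices`, per-view mass added) and
#'   `corrections` (data frame of amplitude boosts, if any).
#' @export
cosine_detruncate <- function(sino, mass_tol = 2e-4, max_iter = 8L) {
  g <- sino$geometry
  gext <- extend_geometry(g)
  rf <- g$source_to_isocenter_mm
  rfd <- g$source_to_detector_mm
  du <- g$channel_spacing_mm
  n_ext <- gext$n_channels
  blk <- centered_block(n_ext, g$n_channels)
  nsl <- dim(sino$values)[3]
  na <- g$n_angles
  tg <- parallel_grid(gext)
  nt <- tg$n

  # parallel channels covered by the measured detector
  u_edge <- (g$n_channels - 1) / 2 * du
  t_edge <- rf * sin(atan(u_edge / rfd))
  jmeas <- which(abs(tg$t) <= t_edge + 1e-9)
  jl <- min(jmeas)
  jr <- max(jmeas)
  ext_l <- if (jl > 1L) (jl - 1L):1L else integer()        # nearest first
  ext_r <- if (jr < nt) (jr + 1L):nt else integer()
  fan_ext_cols <- c(if (blk[1] > 1L) 1L:(blk[1] - 1L) else integer(),
                    if (blk[2] < n_ext) (blk[2] + 1L):n_ext else integer())

  vals <- array(0, c(na, n_ext, nsl))
  vals[, blk[1]:blk[2], ] <- sino$values
  added <- matrix(0, na, nsl)
  corrections <- list()

  for (k in seq_len(nsl)) {
    fan0 <- vals[, , k]
    par0 <- rebin_fan_to_parallel(fan0, gext, tg)
    m0 <- rowSums(par0) * tg$dt
    ref <- max(m0)
    if (ref <= 0) stop("all-zero sinogram: projection mass undefined")
    deficit <- ref - m0
    if (any(deficit < -mass_tol * ref))
      stop("negative mass deficit: reference mis-selected")
    p_l <- par0[, jl]
    p_r <- par0[, jr]
    edge_sum <- p_l + p_r
    act <- deficit > 1e-6 * ref & edge_sum > 0
    if (!any(act)) next

    ext <- matrix(0, na, nt)          # parallel-domain lobes
    for (side in c("left", "right")) {
      p_edge <- if (side == "left") p_l else p_r
      cols <- if (side == "left") ext_l else ext_r
      if (!length(cols)) next
      use <- which(act & p_edge > 0)
      if (!length(use)) next
      target <- deficit[use] * p_edge[use] / edge_sum[use]
      d <- seq_along(cols) * tg$dt
      wts <- rep(tg$dt, length(cols))
      sol <- solve_cos2_width(target, p_edge[use], d, wts)
      for (ii in seq_along(use)) {
        ext[use[ii], cols] <- sol$amp[ii] *
          cos((pi / 2) * pmin(d / sol$width[ii], 1))^2 * (d < sol$width[ii])
        if (sol$boost[ii] > 1.001)
          corrections[[length(corrections) + 1L]] <-
            data.frame(slice = k, view = use[ii], side = side,
                       boost = sol$boost[ii])
      }
    }

    # map lobes onto fan extension channels; rescale until the fan
    # sinogram's mass profile is flat
    s <- rep(1, na)
    fan_k <- fan0
    for (it in seq_len(max_iter)) {
      fan_k[, fan_ext_cols] <-
        rebin_parallel_to_fan(par0 + ext * s, gext, tg, fan_ext_cols)
      m <- rowSums(rebin_fan_to_parallel(fan_k, gext, tg)) * tg$dt
      if (max(abs(m - ref)) <= mass_tol * ref) break
      a_got <- m - m0
      idx <- act & a_got > 1e-12 * ref
      s[idx] <- s[idx] * deficit[idx] / a_got[idx]
    }
    vals[, , k] <- fan_k
    added[, k] <- m - m0
  }

  mask <- rep(FALSE, n_ext)
  mask[blk[1]:blk[2]] <- sino$measured_mask
  res <- list(sinogram = sinogram(vals, gext, mask), added_mass = added,
              corrections = if (length(corrections))
                do.call(rbind, corrections) else NULL)
  class(res) <- "detruncation_result"
  res
}

# Solve for the cos^2 lobe width W (vectorized bisection over angles) such
# that amp * sum_{d_j < W} cos^2((pi/2) d_j / W) * wts_j == target.
# If the bore-wide maximum width is insufficient, boost the amplitude.
solve_cos2_width <- function(target, amp, d, wts) {
  wmax <- max(d) + (if (length(d) > 1) d[2] - d[1] else d[1])
  mass_at <- function(w) {
    # w: vector over cases; returns added mass per case
    frac <- outer(d, w, "/")
    m <- cos((pi / 2) * pmin(frac, 1))^2 * (frac < 1)
    amp * colSums(m * wts)
  }
  n <- length(target)
  lo <- rep(1e-6, n)
  hi <- rep(wmax, n)
  m_hi <- mass_at(hi)
  boost <- pmax(target / m_hi, 1)
  target_eff <- pmin(target, m_hi)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    m <- mass_at(mid)
    takehi <- m > target_eff
    hi[takehi] <- mid[takehi]
    lo[!takehi] <- mid[!takehi]
  }
  width <- (lo + hi) / 2
  width[boost > 1] <- wmax
  list(width = width, amp = amp * boost, boost = boost)
}

#' Linear-times-cosine-squared detruncation
#'
#' The extrapolation used to prepare network input reconstructions: each
#' truncated row is continued with
#' `p(u_edge + d) = max(0, p_edge + s*d) * cos^2((pi/2) d / W_bore)`,
#' where `s` is the one-sided finite-difference slope at the edge channel
#' and `W_bore` is the distance from the edge to the end of the bore-wide
#' channel grid, so the extension reaches zero at the bore.  Intended as
#' `conv_only_extension` for [fbp_reconstruct()]: the extrapolated data
#' take part in the convolution only, never in the backprojection.
#'
#' @param sino A [sinogram()].
#' @return A `detruncation_result` (see [cosine_detruncate()]).
#' @export
linear_cos2_detruncate <- function(sino) {
  g <- sino$geometry
  gext <- extend_geometry(g)
  du <- g$channel_spacing_mm
  n_ext <- gext$n_channels
  blk <- centered_block(n_ext, g$n_channels)
  dists <- extension_distances(n_ext, blk, du)
  uext <- channel_offsets(gext)
  wext <- fan_parallel_weight(gext, uext) * du
  nsl <- dim(sino$values)[3]
  na <- g$n_angles
  vals <- array(0, c(na, n_ext, nsl))
  vals[, blk[1]:blk[2], ] <- sino$values
  added <- matrix(0, na, nsl)
  eps <- 1e-9
  for (k in seq_len(nsl)) {
    for (side in c("left", "right")) {
      d <- dists[[side]]
      if (!length(d)) next
      wbore <- max(d) + du
      if (side == "left") {
        p_edge <- sino$values[, 1L, k]
        slope <- (sino$values[, 1L, k] - sino$values[, 2L, k]) / du
        cols <- (blk[1] - 1L):1L
        wts <- rev(wext[seq_len(blk[1] - 1L)])
      } else {
        nc <- g$n_channels
        p_edge <- sino$values[, nc, k]
        slope <- (sino$values[, nc, k] - sino$values[, nc - 1L, k]) / du
        cols <- (blk[2] + 1L):n_ext
        wts <- wext[(blk[2] + 1L):n_ext]
      }
      lin <- pmax(outer(p_edge, rep(1, length(d))) + outer(slope, d), 0)
      prof <- lin * rep(cos((pi / 2) * d / wbore)^2, each = na)
      prof[p_edge <= eps, ] <- 0
      vals[, cols, k] <- prof
      added[, k] <- added[, k] + prof %*% wts
    }
  }
  mask <- rep(FALSE, n_ext)
  mask[blk[1]:blk[2]] <- sino$measured_mask
  res <- list(sinogram = sinogram(vals, gext, mask), added_mass = added,
              corrections = NULL)
  class(res) <- "detruncation_result"
  res
}

#' Smooth and binarize an image into an object mask
#'
#' Gaussian low-pass in-plane (`sigma_mm`) and across slices
#' (`sigma_slices`, in slice units) to ensure smooth outer contours, then
#' thresholding; only the largest connected component per slice is kept
#' and its holes are filled.
#'
#' @param image A [ct_image()] in HU.
#' @param sigma_mm In-plane Gaussian sigma (mm); 0 disables.
#' @param sigma_slices Cross-slice Gaussian sigma (slices); 0 disables.
#' @param threshold_hu Binarization threshold (HU).
#' @return A `ct_mask` (logical `ct_image`-shaped object).  Signals a
#'   condition of class `efovct_empty_mask` if no voxel exceeds the
#'   threshold.
#' @export
binarize_object <- function(image, sigma_mm = 5, sigma_slices = 1,
                            threshold_hu = -400) {
  stopifnot(sigma_mm >= 0, sigma_slices >= 0)
  vals <- image$values
  ns <- dim(vals)[3]
  if (sigma_mm > 0) {
    sp <- sigma_mm / image$pixel_spacing_mm
    for (k in seq_len(ns))
      vals[, , k] <- as.array(EBImage::gblur(vals[, , k], sigma = sp))
  }
  if (sigma_slices > 0 && ns > 1) {
    r <- max(1L, ceiling(3 * sigma_slices))
    kern <- exp(-(seq(-r, r))^2 / (2 * sigma_slices^2))
    kern <- kern / sum(kern)
    sm <- array(0, dim(vals))
    for (off in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(ns) + off, 1L), ns)   # replicate boundary
      sm <- sm + kern[off + r + 1L] * vals[, , idx, drop = FALSE]
    }
    vals <- sm
  }
  bin <- vals > threshold_hu
  if (!any(bin))
    stop(structure(list(message = "no voxel above threshold",
                        call = sys.call()),
                   class = c("efovct_empty_mask", "error", "condition")))
  for (k in seq_len(ns)) bin[, , k] <- largest_component_filled(bin[, , k])
  mask <- list(values = bin, pixel_spacing_mm = image$pixel_spacing_mm,
               slice_thickness_mm = image$slice_thickness_mm,
               origin = image$origin)
  class(mask) <- c("ct_mask", "ct_image")
  mask
}

largest_component_filled <- function(slice) {
  if (!any(slice)) return(slice)
  lab <- EBImage::bwlabel(slice)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  as.array(EBImage::fillHull(keep)) > 0
}

#' Forward-project a binary object mask as water
#'
#' The mask is treated as water-filled (`mu = mu_water_per_mm` inside, 0
#' outside) and forward-projected on the bore-wide extended channel grid
#' of `geometry`.
#'
#' @param mask A `ct_mask` (e.g. from [binarize_object()]).
#' @param geometry Physical [scan_geometry()].
#' @param mu_water_per_mm Water attenuation (1/mm).
#' @return A [sinogram()] on the extended grid, all channels flagged
#'   measured.
#' @export
mask_to_sinogram <- function(mask, geometry, mu_water_per_mm = 0.02) {
  img <- list(values = array(as.numeric(mask$values), dim(mask$values)) *
                mu_water_per_mm,
              pixel_spacing_mm = mask$pixel_spacing_mm,
              slice_thickness_mm = mask$slice_thickness_mm,
              origin = mask$origin)
  class(img) <- "ct_image"
  forward_project(img, extend_geometry(geometry), values_are = "mu",
                  mu_water_per_mm = mu_water_per_mm)
}

#' Merge measured and simulated sinograms in the projection domain
#'
#' The output equals the measured data on the measured channels
#' (bit-exactly) and the simulated data elsewhere.  A feathering window of
#' `feather` channels on the simulated side of each junction decays the
#' boundary jump (measured edge value minus adjacent simulated value)
#' linearly to zero, smoothing the junction without touching measured
#' values; where the junction is already continuous (e.g. objects fully
#' inside the sFoV, where both sides are zero) it is a no-op.
#'
#' @param measured A [sinogram()] on the physical detector.
#' @param simulated A [sinogram()] on an extended grid with the same
#'   spacing, angles and slice count.
#' @param feather Feathering width in channels (0 disables).
#' @return A merged [sinogram()] on the extended grid whose
#'   `measured_mask` marks the measured block.
#' @export
merge_sinograms <- function(measured, simulated, feather = 3) {
  g <- measured$geometry
  ge <- simulated$geometry
  if (ge$n_angles != g$n_angles ||
      !isTRUE(all.equal(ge$channel_spacing_mm, g$channel_spacing_mm)) ||
      ge$n_channels < g$n_channels ||
      dim(simulated$values)[3] != dim(measured$values)[3])
    stop("measured/simulated sinogram grids do not match")
  blk <- centered_block(ge$n_channels, g$n_channels)
  vals <- simulated$values
  vals[, blk[1]:blk[2], ] <- measured$values
  if (feather > 0) {
    for (k in seq_len(dim(vals)[3])) {
      if (blk[1] > 1L) {
        jump <- measured$values[, 1L, k] - simulated$values[, blk[1] - 1L, k]
        for (j in seq_len(min(feather, blk[1] - 1L)))
          vals[, blk[1] - j, k] <- vals[, blk[1] - j, k] +
            jump * (feather - j + 1) / (feather + 1)
      }
      if (blk[2] < ge$n_channels) {
        nc <- g$n_channels
        jump <- measured$values[, nc, k] - simulated$values[, blk[2] + 1L, k]
        for (j in seq_len(min(feather, ge$n_channels - blk[2])))
          vals[, blk[2] + j, k] <- vals[, blk[2] + j, k] +
            jump * (feather - j + 1) / (feather + 1)
      }
    }
  }
  mask <- rep(FALSE, ge$n_channels)
  mask[blk[1]:blk[2]] <- measured$measured_mask
  sinogram(vals, ge, mask)
}

#' HDFoV reconstruction (mass-consistency detruncation pipeline)
#'
#' Two-step extended-FoV pipeline: (1) cosine mass-consistency
#' detruncation and a first-pass bore-wide reconstruction; (2) Gaussian
#' smoothing and binarization of the first pass into an object mask,
#' forward projection of the mask as water, projection-domain merge with
#' the measured data (measured channels untouched), and the final
#' reconstruction.
#'
#' @param measured A [sinogram()] on the physical detector.
#' @param fov_mm,matrix Final reconstruction grid.
#' @param first_pass_matrix Matrix size of the intermediate bore-wide
#'   reconstruction.
#' @param sigma_mm,sigma_slices,threshold_hu Passed to
#'   [binarize_object()].
#' @param feather Passed to [merge_sinograms()].
#' @param filter Ramp apodization for both passes.
#' @param save_intermediates If `TRUE`, attach the detruncation result,
#'   first-pass image, mask and merged sinogram as the `intermediates`
#'   attribute.
#' @return A [ct_image()].  If the first-pass mask is empty the function
#'   falls back to the cosine-detruncated reconstruction with a warning.
#' @export
hdfov_reconstruct <- function(measured, fov_mm = 800, matrix = 512,
                              first_pass_matrix = 256, sigma_mm = 5,
                              sigma_slices = 1, threshold_hu = -400,
                              feather = 3, filter = "ramlak",
                              save_intermediates = FALSE) {
  det <- cosine_detruncate(measured)
  first <- fbp_reconstruct(det$sinogram, fov_mm = 2 *
                             measured$geometry$bore_radius_mm,
                           matrix = first_pass_matrix, filter = filter)
  mask <- tryCatch(
    binarize_object(first, sigma_mm, sigma_slices, threshold_hu),
    efovct_empty_mask = function(e) NULL)
  if (is.null(mask)) {
    warning("empty first-pass object mask; falling back to the ",
            "cosine-detruncated reconstruction")
    return(fbp_reconstruct(det$sinogram, fov_mm = fov_mm, matrix = matrix,
                           filter = filter))
  }
  sim <- mask_to_sinogram(mask, measured$geometry)
  merged <- merge_sinograms(measured, sim, feather = feather)
  out <- fbp_reconstruct(merged, fov_mm = fov_mm, matrix = matrix,
                         filter = filter)
  if (save_intermediates)
    attr(out, "intermediates") <- list(detruncation = det, first_pass = first,
                                       mask = mask, merged = merged)
  out
}
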