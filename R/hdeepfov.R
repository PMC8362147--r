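#' Image-domain eFoV estimators
#'
#' An estimator is a callable contract mapping a 256 x 256 HU image on an
#' 800 mm field of view to an image on the identical grid; its output is
#' clipped to \[-1000, 3000\] HU.  Three kinds exist: `identity` (passes
#' the input through; lower baseline), `oracle` (returns the true image,
#' the upper bound used to validate the pipeline), and `trained` (a
#' fitted U-Net, see [train_estimator()]).
#'
#' @param kind One of `"identity"`, `"oracle"`, `"trained"`.
#' @param fn Function `ct_image -> ct_image` on the fixed grid.
#' @param meta List of metadata (training log, config, ...).
#' @return An object of class `efov_estimator`.
#' @export
new_estimator <- function(kind, fn, meta = list()) {
  stopifnot(kind %in% c("identity", "oracle", "trained"), is.function(fn))
  est <- list(kind = kind, fn = fn, meta = meta)
  class(est) <- "efov_estimator"
  est
}

#' @export
print.efov_estimator <- function(x, ...) {
  cat(sprintf("<efov_estimator> kind: %s\n", x$kind))
  invisible(x)
}

#' @rdname new_estimator
#' @export
estimator_identity <- function() new_estimator("identity", function(img) img)

#' @rdname new_estimator
#' @param truth A [ct_image()] of the true object over 800 mm; resampled
#'   to the 256 x 256 estimator grid (area averaging when the matrix size
#'   is a multiple of 256, bilinear otherwise).
#' @export
estimator_oracle <- function(truth) {
  n <- dim(truth$values)[1]
  if (n != 256) {
    if (n %% 256 == 0) {
      truth <- downsample_image(truth, 256)
    } else {
      sp <- 800 / 256
      xq <- (seq_len(256) - 257 / 2) * sp
      xs <- image_axis(truth, 1)
      ys <- image_axis(truth, 2)
      vals <- array(-1000, c(256, 256, n_slices(truth)))
      for (k in seq_len(n_slices(truth)))
        vals[, , k] <- bilinear_grid(truth$values[, , k], xs, ys, xq, xq)
      truth <- ct_image(vals, sp, truth$slice_thickness_mm)
    }
  }
  force(truth)
  new_estimator("oracle", function(img) {
    out <- truth
    if (n_slices(out) != n_slices(img))
      stop("oracle truth slice count does not match the input")
    out
  })
}

#' Apply an estimator under the interface contract
#'
#' Validates the 256 x 256 / 800 mm input grid, calls the estimator, and
#' validates and HU-clips the output.
#'
#' @param estimator An [new_estimator()].
#' @param image Input [ct_image()] (256 x 256 over 800 mm).
#' @return The estimated [ct_image()] on the identical grid, HU in
#'   \[-1000, 3000\].
#' @export
apply_estimator <- function(estimator, image) {
  stopifnot(inherits(estimator, "efov_estimator"),
            inherits(image, "ct_image"))
  d <- dim(image$values)
  if (d[1] != 256 || d[2] != 256 ||
      !isTRUE(all.equal(image$pixel_spacing_mm, 800 / 256)))
    stop("estimator input must be 256 x 256 over 800 mm")
  out <- estimator$fn(image)
  if (!inherits(out, "ct_image") ||
      !identical(dim(out$values)[1:2], d[1:2]) ||
      dim(out$values)[3] != d[3] ||
      !isTRUE(all.equal(out$pixel_spacing_mm, image$pixel_spacing_mm)))
    stop("estimator output grid does not match its input grid")
  out$values <- pmin(pmax(out$values, -1000), 3000)
  out
}

#' Prepare the network input image from measured data
#'
#' Reconstructs the measured sinogram with the linear-times-cos^2
#' extrapolation used during the convolution step only (backprojection of
#' measured channels only), on an 800 mm field of view, and downsamples
#' the result to 256 x 256 by area averaging.  The identical procedure is
#' used to build training inputs and at inference time.
#'
#' @param measured A [sinogram()] on the physical detector.
#' @param recon_matrix Matrix size of the intermediate reconstruction
#'   (must be a multiple of `out_size`).
#' @param out_size Output matrix size (the estimator grid).
#' @param filter Ramp apodization.
#' @return A [ct_image()], `out_size` x `out_size` over 800 mm.
#' @export
prepare_network_input <- function(measured, recon_matrix = 512,
                                  out_size = 256, filter = "ramlak") {
  det <- linear_cos2_detruncate(measured)
  img <- fbp_reconstruct(measured, fov_mm = 800, matrix = recon_matrix,
                         filter = filter,
                         conv_only_extension = det$sinogram)
  if (recon_matrix != out_size) img <- downsample_image(img, out_size)
  img
}

#' HDeepFoV reconstruction (projection-domain fusion pipeline)
#'
#' Builds the network input image from the measured data, obtains an
#' image-domain estimate of the full object from the estimator, forward
#' projects the estimate on the bore-wide channel grid, fuses it with the
#' measured data in the projection domain (measured channels preserved
#' bit-exactly), and reconstructs the fused sinogram with standard
#' filtered backprojection.  No image-domain scaling or blending is
#' applied; the estimate only enters through the projector, so the final
#' image is a genuine `matrix`-sized reconstruction, never an upsampled
#' network output.
#'
#' @param measured A [sinogram()] on the physical detector.
#' @param estimator An [new_estimator()].
#' @param fov_mm,matrix,filter Final reconstruction settings (any
#'   standard kernel may be used here).
#' @param feather Passed to [merge_sinograms()].
#' @param recon_matrix Intermediate matrix for
#'   [prepare_network_input()].
#' @param save_intermediates Attach network input/estimate and the fused
#'   sinogram as the `intermediates` attribute.
#' @return A [ct_image()].
#' @export
hdeepfov_reconstruct <- function(measured, estimator, fov_mm = 800,
                                 matrix = 512, filter = "ramlak",
                                 feather = 3, recon_matrix = 512,
                                 save_intermediates = FALSE) {
  net_in <- prepare_network_input(measured, recon_matrix = recon_matrix)
  est <- apply_estimator(estimator, net_in)
  sim <- forward_project(est, extend_geometry(measured$geometry),
                         values_are = "hu")
  merged <- merge_sinograms(measured, sim, feather = feather)
  out <- fbp_reconstruct(merged, fov_mm = fov_mm, matrix = matrix,
                         filter = filter)
  if (save_intermediates)
    attr(out, "intermediates") <- list(network_input = net_in,
                                       estimate = est, merged = merged)
  out
}
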