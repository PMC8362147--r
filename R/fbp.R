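#' Filtered backprojection for flat-detector fan-beam data
#'
#' Standard full-scan (360 degree) filtered backprojection: cosine
#' pre-weighting on the virtual detector through the isocenter, row
#' convolution with a band-limited ramp kernel (optionally apodized), and
#' distance-weighted backprojection.  Before filtering, the channel grid is
#' symmetrically zero-extended so that it covers the bore; supplying
#' `conv_only_extension` instead fills that extension with extrapolated
#' data that take part in the convolution only, while the backprojection is
#' restricted to the measured channels (the convolution-only extrapolation
#' scheme used to prepare network input images).
#'
#' @param sino A [sinogram()].
#' @param fov_mm Reconstructed field of view (mm); at most the bore
#'   diameter.
#' @param matrix Output matrix size (>= 32).
#' @param filter Ramp apodization: plain band-limited ramp (`"ramlak"`,
#'   default), `"shepp-logan"`, `"cosine"` or `"hamming"`.
#' @param conv_only_extension Optional [sinogram()] on an extended channel
#'   grid (same angles, spacing and slice count, wider centered channel
#'   block) whose values are used during filtering only; implies
#'   `backproject = "measured"`.
#' @param backproject `"all"` (default) backprojects every channel of the
#'   (extended) grid; `"measured"` restricts backprojection to the block
#'   flagged by the sinogram's `measured_mask`.
#' @param mu_water_per_mm Water attenuation for the HU scale.
#' @return A [ct_image()] of `matrix x matrix x n_slices` HU values over
#'   `fov_mm`, centered at the isocenter.
#' @export
fbp_reconstruct <- function(sino, fov_mm = 800, matrix = 512,
                            filter = c("ramlak", "shepp-logan", "cosine",
                                       "hamming"),
                            conv_only_extension = NULL,
                            backproject = c("all", "measured"),
                            mu_water_per_mm = 0.02) {
  filter <- match.arg(filter)
  backproject <- match.arg(backproject)
  g <- sino$geometry
  stopifnot(matrix >= 32)
  if (fov_mm > 2 * g$bore_radius_mm)
    stop("fov_mm exceeds the bore diameter")
  if (g$n_angles < 8) stop("too few projection angles for a full rotation")

  if (!is.null(conv_only_extension)) {
    if (inherits(conv_only_extension, "detruncation_result"))
      conv_only_extension <- conv_only_extension$sinogram
    ge <- conv_only_extension$geometry
    if (ge$n_angles != g$n_angles ||
        !isTRUE(all.equal(ge$channel_spacing_mm, g$channel_spacing_mm)) ||
        dim(conv_only_extension$values)[3] != dim(sino$values)[3] ||
        ge$n_channels < g$n_channels)
      stop("conv_only_extension shape does not match the sinogram")
    blk <- centered_block(ge$n_channels, g$n_channels)
    mask <- rep(FALSE, ge$n_channels)
    mask[(blk[1]:blk[2])[sino$measured_mask]] <- TRUE
    ext <- sinogram(conv_only_extension$values, ge, mask)
    backproject <- "measured"
  } else {
    gext <- extend_geometry(g)
    if (gext$n_channels > g$n_channels) {
      blk <- centered_block(gext$n_channels, g$n_channels)
      vals <- array(0, c(g$n_angles, gext$n_channels, dim(sino$values)[3]))
      vals[, blk[1]:blk[2], ] <- sino$values
      mask <- rep(FALSE, gext$n_channels)
      mask[(blk[1]:blk[2])[sino$measured_mask]] <- TRUE
      ext <- sinogram(vals, gext, mask)
    } else {
      ext <- sino
    }
  }

  rf <- g$source_to_isocenter_mm
  rfd <- g$source_to_detector_mm
  s <- channel_offsets(ext$geometry) * rf / rfd    # virtual detector at iso
  ds <- ext$geometry$channel_spacing_mm * rf / rfd
  wcos <- rf / sqrt(rf^2 + s^2)
  ns <- length(s)
  kf <- ramp_kernel_fft(ns, ds, filter)
  nfft <- length(kf)

  if (backproject == "measured") {
    jr <- measured_range(ext)
  } else {
    jr <- c(1L, ns)
  }

  nsl <- dim(ext$values)[3]
  out <- array(0, c(matrix, matrix, nsl))
  for (k in seq_len(nsl)) {
    vw <- t(ext$values[, , k] * rep(wcos, each = g$n_angles))   # ns x na
    vpad <- matrix(0, nfft, g$n_angles)
    vpad[seq_len(ns), ] <- vw
    q <- Re(stats::mvfft(stats::mvfft(vpad) * kf, inverse = TRUE)) / nfft
    q <- t(q[seq_len(ns), , drop = FALSE]) * ds                 # na x ns
    mu <- .bp_slice(q, g$angles_rad, s[1], ds, rf, as.integer(matrix),
                    fov_mm, jr[1] - 1L, jr[2] - 1L)
    out[, , k] <- mu
  }
  img <- ct_image(pmax(1000 * (out / mu_water_per_mm - 1), -1000),
                  fov_mm / matrix, origin = c(0, 0))
  img
}

# FFT of the band-limited discrete ramp kernel (Ram-Lak), optionally
# apodized, laid out for circular convolution on nfft samples.
ramp_kernel_fft <- function(ns, ds, filter = "ramlak") {
  nfft <- stats::nextn(2L * ns, 2)
  h <- numeric(nfft)
  k <- seq_len(ns - 1)
  hk <- ifelse(k %% 2 == 1, -1 / (pi * k * ds)^2, 0)
  h[1] <- 1 / (4 * ds^2)
  h[1 + k] <- hk
  h[nfft + 1 - k] <- hk
  kf <- stats::fft(h)
  if (filter != "ramlak") {
    f <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / (nfft / 2)  # |freq|/f_N
    win <- switch(filter,
      "shepp-logan" = ifelse(f == 0, 1, sin(pi * f / 2) / (pi * f / 2)),
      "cosine" = cos(pi * f / 2),
      "hamming" = 0.54 + 0.46 * cos(pi * f))
    kf <- kf * win
  }
  kf
}
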