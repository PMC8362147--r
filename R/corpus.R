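#' Random body-like slice specification
#'
#' Draws a procedural body-like slice for estimator training: an
#' elliptical body that exceeds the sFoV (half-width beyond 250 mm) while
#' fitting inside the bore, two low-density lung ellipses, and a few
#' random higher/lower-density circular structures.  Scale, rotation and
#' shift are drawn per slice so the corpus covers varied poses; the
#' transform is applied analytically to the component parameters, so the
#' exact ground-truth body mask stays available.
#'
#' @param seed Integer seed (one draw is fully determined by it).
#' @param bore_radius_mm,sfov_radius_mm Constraints: the body must fit
#'   inside the bore and extend beyond the sFoV.
#' @return A [phantom_spec()] (single slice).
#' @export
random_body_spec <- function(seed, bore_radius_mm = 400,
                             sfov_radius_mm = 250) {
  withr::with_seed(seed, {
    repeat {
      a <- runif(1, sfov_radius_mm + 10, 330)
      b <- runif(1, 105, 255)
      rot <- runif(1, 0, pi)
      cx <- runif(1, -45, 45)
      cy <- runif(1, -70, 70)
      if (sqrt(cx^2 + cy^2) + max(a, b) <= bore_radius_mm - 5 &&
          sqrt(cx^2 + cy^2) + a > sfov_radius_mm + 10) break
    }
    body_hu <- runif(1, 10, 120)
    lung_hu <- -runif(2, 550, 850)
    lx <- runif(1, 0.32, 0.45) * a
    comps <- data.frame(
      shape = "ellipse",
      cx = cx + c(0, lx * cos(rot), -lx * cos(rot)),
      cy = cy + c(0, lx * sin(rot), -lx * sin(rot)),
      ax = c(a, runif(2, 0.22, 0.32) * a),
      ay = c(b, runif(2, 0.35, 0.55) * b),
      rot = rot + c(0, runif(2, -0.2, 0.2)),
      hu = c(body_hu, lung_hu))
    n_extra <- sample(0:3, 1)
    if (n_extra > 0) {
      th <- runif(n_extra, 0, 2 * pi)
      rr <- runif(n_extra, 0, 0.45)
      ex <- cx + rr * a * cos(th) * cos(rot) - rr * b * sin(th) * sin(rot)
      ey <- cy + rr * a * cos(th) * sin(rot) + rr * b * sin(th) * cos(rot)
      comps <- rbind(comps, data.frame(
        shape = "circle", cx = ex, cy = ey,
        ax = runif(n_extra, 8, 32), ay = 0, rot = 0,
        hu = runif(n_extra, -300, 1100)))
    }
    phantom_spec(comps, n_slices = 1L, slice_thickness_mm = 3,
                 bore_radius_mm = bore_radius_mm)
  })
}

#' Generate one training pair
#'
#' Rasterizes the random ground-truth slice on the 800 mm grid, simulates
#' the truncated acquisition (forward projection on the bore-covering
#' detector, truncation to the physical detector), and reconstructs the
#' network input with the convolution-only linear-times-cos^2
#' extrapolation.  Bit-identical output for the same `(config, index)`.
#'
#' @param config A [training_config()].
#' @param index Pair index (1-based).
#' @param with_sinogram Keep the truncated measured sinogram in the pair
#'   (needed to run reconstruction pipelines on corpus members).
#' @return A list with `input` and `target` ([ct_image()], 256 x 256 over
#'   800 mm), `spec` (the analytic [phantom_spec()]), `seed`, and
#'   optionally `sinogram`.
#' @export
corpus_pair <- function(config, index, with_sinogram = FALSE) {
  seed_i <- (config$seed + 7919L * as.integer(index)) %% 2147483647L
  spec <- random_body_spec(seed_i,
                           bore_radius_mm = config$geometry$bore_radius_mm,
                           sfov_radius_mm = config$geometry$sfov_radius_mm)
  truth <- rasterize_phantom(spec, matrix = 256, fov_mm = 800)
  # one-pixel sampling step: adequate for training data, halves the cost
  ext <- forward_project(truth, extend_geometry(config$geometry),
                         step_mm = truth$pixel_spacing_mm)
  measured <- truncate_sinogram(ext, config$geometry)
  input <- prepare_network_input(measured,
                                 recon_matrix = config$recon_matrix)
  pair <- list(input = input, target = truth, spec = spec, seed = seed_i)
  if (with_sinogram) pair$sinogram <- measured
  pair
}

#' Generate a synthetic training corpus
#'
#' `config$n_pairs` training pairs via [corpus_pair()]; the procedure can
#' emit an unlimited number of pairs, the desk-scale default being
#' hundreds.
#'
#' @param config A [training_config()].
#' @param with_sinograms Keep measured sinograms in every pair (memory
#'   heavy; regenerate individual pairs on demand instead where
#'   possible).
#' @param progress Print a dot every 50 pairs.
#' @return An object of class `training_corpus`: list with `pairs` and
#'   `config`.
#' @export
generate_training_corpus <- function(config, with_sinograms = FALSE,
                                     progress = FALSE) {
  stopifnot(inherits(config, "training_config"))
  pairs <- vector("list", config$n_pairs)
  for (i in seq_len(config$n_pairs)) {
    pairs[[i]] <- corpus_pair(config, i, with_sinogram = with_sinograms)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- list(pairs = pairs, config = config)
  class(out) <- "training_corpus"
  out
}

#' @export
print.training_corpus <- function(x, ...) {
  cat(sprintf("<training_corpus> %d pairs (seed %d)\n", length(x$pairs),
              x$config$seed))
  invisible(x)
}
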