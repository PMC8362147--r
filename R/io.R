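#' Array-container input/output
#'
#' Sinograms, images, masks and reports are stored in a versioned
#' container based on R's native serialization, carrying the full object
#' (arrays plus all metadata fields); write-then-read round-trips are
#' bit-exact.  `write_ct_image()`/`write_sinogram()` are thin class-checked
#' wrappers.
#'
#' @param x Object to store.
#' @param path File path (conventionally `.rds`).
#' @return `read_container` returns the stored object.
#' @export
write_container <- function(x, path) {
  saveRDS(list(format = "efovct_container", version = 1L,
               class = class(x), payload = x), path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "efovct_container"))
    stop("not an efovct container: ", path)
  obj$payload
}

#' @rdname write_container
#' @export
write_ct_image <- function(x, path) {
  stopifnot(inherits(x, "ct_image"))
  write_container(x, path)
}

#' @rdname write_container
#' @export
read_ct_image <- function(path) {
  x <- read_container(path)
  stopifnot(inherits(x, "ct_image"))
  x
}

#' @rdname write_container
#' @export
write_sinogram <- function(x, path) {
  stopifnot(inherits(x, "sinogram"))
  write_container(x, path)
}

#' @rdname write_container
#' @export
read_sinogram <- function(path) {
  x <- read_container(path)
  stopifnot(inherits(x, "sinogram"))
  x
}

#' Export an image slice as a lossless TIFF for inspection
#'
#' @param image A [ct_image()].
#' @param path Output path.
#' @param slice Slice index.
#' @param window HU display window, clipped and mapped to \[0, 1\].
#' @export
export_slice_tiff <- function(image, path, slice = 1L,
                              window = c(-1000, 1000)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF export")
  v <- image$values[, , slice]
  v <- (pmin(pmax(v, window[1]), window[2]) - window[1]) / diff(window)
  tiff::writeTIFF(t(v)[nrow(v):1, , drop = FALSE], path)
  invisible(path)
}

#' Run configuration
#'
#' Declarative configuration for [run_experiment()] and the command-line
#' interface, with blocks for the scan geometry, the phantom, the
#' reconstruction, the evaluation protocol and training.  Every field
#' has a materialized default; unknown keys are rejected so that typos
#' never pass silently.
#'
#' @param ... Named blocks overriding the defaults (nested lists).
#' @return An object of class `run_config` with all defaults
#'   materialized.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    outdir = NULL,
    geometry = list(source_to_isocenter_mm = 595,
                    source_to_detector_mm = 1086, n_channels = 504,
                    channel_spacing_mm = 2, n_angles = 720,
                    sfov_radius_mm = 250, bore_radius_mm = 400),
    phantom = list(width_mm = 560, height_mm = 270, body_hu = 100,
                   lung_hu = -700, insert = NULL, insert_radius_mm = 15,
                   n_slices = 3L, slice_thickness_mm = 18,
                   pixel_spacing_mm = 800 / 512),
    reconstruction = list(algorithms = c("naive", "hdfov", "hdeepfov"),
                          estimator = "oracle", fov_mm = 800, matrix = 512,
                          filter = "ramlak", first_pass_matrix = 256,
                          sigma_mm = 5, sigma_slices = 1,
                          threshold_hu = -400, feather = 3),
    evaluation = list(couch_heights_mm = c(0, 90, 120),
                      lateral_shift_mm = 60, threshold_hu = -400,
                      bin_width_hu = 10, stitched = TRUE,
                      roi_radius_mm = 10, roi_n_slices = 5),
    training = list(n_pairs = 500L, net_size = 64L, base_channels = 8L,
                    leaky_slope = 0.01, learning_rate = 1e-3,
                    batch_size = 10L, epochs = 30L, val_fraction = 0.2,
                    recon_matrix = 256L, n_angles = 144L,
                    n_channels = 252L, channel_spacing_mm = 4,
                    checkpoint_path = NULL))
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(defaults, override, path) {
  if (length(override) == 0) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste(path, unknown, sep = ".")),
                collapse = ", "))
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(override[[k]]),
                                    paste(path, k, sep = "."))
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys follow [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Write the resolved configuration of a run
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# geometry / training_config constructors from a run_config
config_geometry <- function(config) do.call(scan_geometry, config$geometry)

config_training <- function(config) {
  tr <- config$training
  training_config(
    n_pairs = tr$n_pairs, seed = config$seed,
    geometry = scan_geometry(n_channels = tr$n_channels,
                             channel_spacing_mm = tr$channel_spacing_mm,
                             n_angles = tr$n_angles),
    recon_matrix = tr$recon_matrix, net_size = tr$net_size,
    base_channels = tr$base_channels, leaky_slope = tr$leaky_slope,
    learning_rate = tr$learning_rate, batch_size = tr$batch_size,
    epochs = tr$epochs, val_fraction = tr$val_fraction,
    checkpoint_path = tr$checkpoint_path)
}
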