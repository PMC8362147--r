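#' Run the full three-couch-height evaluation experiment
#'
#' Simulates truncated acquisitions of the synthetic thorax phantom at
#' the configured couch heights (default 0, +90, +120 mm), reconstructs
#' each with the configured algorithms (naive zero-padded FBP, HDFoV,
#' HDeepFoV), builds the stitched two-scan reference, and evaluates
#' every reconstruction against both the analytic ground-truth mask and
#' the stitched reference: per-slice eFoV-restricted Jaccard indices,
#' per-slice eFoV volumes and their RMSD across all slices and heights,
#' insert HU statistics (when an insert is configured) and eFoV HU
#' histograms.
#'
#' @param config A [run_config()] (or list of overrides passed to it).
#' @return An object of class `eval_report`.
#' @export
run_experiment <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  geom <- config_geometry(config)
  ph_cfg <- config$phantom
  spec <- thorax_spec(width_mm = ph_cfg$width_mm,
                      height_mm = ph_cfg$height_mm,
                      body_hu = ph_cfg$body_hu, lung_hu = ph_cfg$lung_hu,
                      insert = ph_cfg$insert,
                      insert_radius_mm = ph_cfg$insert_radius_mm,
                      n_slices = ph_cfg$n_slices,
                      slice_thickness_mm = ph_cfg$slice_thickness_mm)
  phantom <- make_thorax_phantom(spec, ph_cfg$pixel_spacing_mm)
  rc <- config$reconstruction
  ev <- config$evaluation
  gext <- extend_geometry(geom)
  matrix <- rc$matrix
  fov <- rc$fov_mm

  reference <- NULL
  ref_vol <- list()
  if (isTRUE(ev$stitched))
    reference <- stitched_reference(phantom, geom,
                                    lateral_shift_mm = ev$lateral_shift_mm,
                                    fov_mm = fov, matrix = matrix,
                                    filter = rc$filter)

  heights <- ev$couch_heights_mm
  res <- list()
  for (h in heights) {
    ph <- shift_couch(phantom, h)
    sino <- truncate_sinogram(forward_project(ph$image, gext), geom)
    truth_mask <- analytic_mask(ph$spec, matrix, fov)
    ref_h <- NULL
    ref_mask_h <- NULL
    if (!is.null(reference)) {
      ref_h <- translate_image(reference, 0, h)
      ref_mask_h <- object_mask(ref_h, ev$threshold_hu)
      ref_vol[[as.character(h)]] <- slice_efov_volume(ref_mask_h, geom)
    }
    for (alg in rc$algorithms) {
      rec <- switch(alg,
        naive = fbp_reconstruct(sino, fov_mm = fov, matrix = matrix,
                                filter = rc$filter),
        hdfov = hdfov_reconstruct(sino, fov_mm = fov, matrix = matrix,
                                  first_pass_matrix = rc$first_pass_matrix,
                                  sigma_mm = rc$sigma_mm,
                                  sigma_slices = rc$sigma_slices,
                                  threshold_hu = rc$threshold_hu,
                                  feather = rc$feather, filter = rc$filter),
        hdeepfov = hdeepfov_reconstruct(
          sino, experiment_estimator(rc$estimator, ph), fov_mm = fov,
          matrix = matrix, filter = rc$filter, feather = rc$feather),
        stop("unknown algorithm: ", alg))
      msk <- object_mask(rec, ev$threshold_hu)
      entry <- list(
        height_mm = h, algorithm = alg,
        jaccard_truth = jaccard_efov(truth_mask, msk, geom),
        jaccard_truth_slices = per_slice_jaccard(truth_mask, msk, geom),
        efov_volume_cm3 = slice_efov_volume(msk, geom),
        truth_volume_cm3 = slice_efov_volume(truth_mask, geom),
        histogram = tryCatch(
          efov_hu_histogram(rec, msk, geom, ev$bin_width_hu),
          efovct_empty_region = function(e) NULL))
      if (!is.null(ref_mask_h)) {
        entry$jaccard_ref <- jaccard_efov(ref_mask_h, msk, geom)
        entry$jaccard_ref_slices <- per_slice_jaccard(ref_mask_h, msk, geom)
        entry$ref_volume_cm3 <- ref_vol[[as.character(h)]]
      }
      if (!is.null(ph_cfg$insert)) {
        pos <- insert_positions(ph$spec)
        entry$insert_hu <- tryCatch(
          roi_hu_stats(rec, pos$top_left, ev$roi_radius_mm,
                       min(ev$roi_n_slices, ph_cfg$n_slices)),
          error = function(e) NULL)
      }
      res[[paste(alg, h, sep = "_")]] <- entry
    }
  }

  report <- list(results = res, couch_heights_mm = heights,
                 algorithms = rc$algorithms, config = config)
  if (!is.null(reference) && !is.null(ph_cfg$insert)) {
    pos <- insert_positions(phantom$spec)
    report$reference_insert_hu <- tryCatch(
      roi_hu_stats(reference, pos$center, ev$roi_radius_mm,
                   min(ev$roi_n_slices, ph_cfg$n_slices)),
      error = function(e) NULL)
  }
  report$volume_rmsd_cm3 <- volume_rmsd_summary(res, rc$algorithms,
                                                !is.null(reference))
  class(report) <- "eval_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

# analytic ground-truth mask rasterized on the reconstruction grid
analytic_mask <- function(spec, matrix, fov_mm) {
  vals <- rasterize_phantom(spec, matrix, fov_mm, "mask")
  mask <- list(values = vals, pixel_spacing_mm = fov_mm / matrix,
               slice_thickness_mm = spec$slice_thickness_mm,
               origin = c(0, 0))
  class(mask) <- c("ct_mask", "ct_image")
  mask
}

per_slice_jaccard <- function(mask_ref, mask_test, geometry) {
  vapply(seq_len(dim(mask_ref$values)[3]), function(k) {
    a <- mask_ref; a$values <- mask_ref$values[, , k, drop = FALSE]
    b <- mask_test; b$values <- mask_test$values[, , k, drop = FALSE]
    as.numeric(jaccard_efov(a, b, geometry))
  }, 0)
}

# in-plane centers of the two inserts (top-left, center) after couch shift
insert_positions <- function(spec) {
  co <- spec$components
  idx <- which(co$shape == "circle")
  if (length(idx) < 2) stop("phantom has no insert pair")
  list(top_left = c(co$cx[idx[1]], co$cy[idx[1]]) + spec$shift,
       center = c(co$cx[idx[2]], co$cy[idx[2]]) + spec$shift)
}

volume_rmsd_summary <- function(res, algorithms, has_ref) {
  out <- list()
  for (alg in algorithms) {
    entries <- Filter(function(e) e$algorithm == alg, res)
    test <- unlist(lapply(entries, `[[`, "efov_volume_cm3"))
    truth <- unlist(lapply(entries, `[[`, "truth_volume_cm3"))
    out[[alg]] <- list(vs_truth = volume_rmsd(truth, test))
    if (has_ref) {
      ref <- unlist(lapply(entries, `[[`, "ref_volume_cm3"))
      out[[alg]]$vs_reference <- volume_rmsd(ref, test)
    }
  }
  out
}

experiment_estimator <- function(kind, phantom) {
  if (inherits(kind, "efov_estimator")) return(kind)
  if (identical(kind, "oracle")) return(estimator_oracle(phantom$image))
  if (identical(kind, "identity")) return(estimator_identity())
  if (is.character(kind) && startsWith(kind, "model:"))
    return(load_estimator(sub("^model:", "", kind)))
  stop("unknown estimator spec: ", kind)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  couch heights (mm): %s\n",
              paste(x$couch_heights_mm, collapse = ", ")))
  for (e in x$results)
    cat(sprintf(
      "  %-9s h=%4.0f mm  eFoV Jaccard vs truth %.3f%s\n",
      e$algorithm, e$height_mm, e$jaccard_truth,
      if (!is.null(e$jaccard_ref))
        sprintf(" (vs reference %.3f)", e$jaccard_ref) else ""))
  for (alg in names(x$volume_rmsd_cm3)) {
    v <- x$volume_rmsd_cm3[[alg]]
    cat(sprintf("  %-9s volume RMSD vs truth %.2f cm^3%s\n", alg,
                v$vs_truth,
                if (!is.null(v$vs_reference))
                  sprintf(", vs reference %.2f cm^3", v$vs_reference)
                else ""))
  }
  invisible(x)
}

# machine-readable report + resolved config
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(report$config, file.path(outdir, "config_resolved.yaml"))
  slim <- report
  slim$config <- NULL
  class(slim) <- NULL
  jsonlite::write_json(slim, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}
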