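#' Structural dissimilarity between two images
#'
#' `DSSIM = (1 - SSIM)/2` with the standard SSIM constants (k1 = 0.01,
#' k2 = 0.03 on data range 1) and an 11-pixel Gaussian window (sigma
#' 1.5).  Local statistics are computed with periodic boundary handling,
#' which makes the windowing self-adjoint so the training gradient is
#' exact.  Inputs are expected in the normalized \[0, 1\] range.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return A single value in \[0, 1\]; 0 iff the images are identical.
#' @export
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' dssim(x, x)   # 0
dssim <- function(a, b) {
  if (inherits(a, "ct_image")) a <- a$values[, , 1]
  if (inherits(b, "ct_image")) b <- b$values[, , 1]
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  .dssim(a, b)
}

# HU <-> normalized [0,1] over [-1000, 3000]
normalize_hu <- function(x) (x + 1000) / 4000
denormalize_hu <- function(x) x * 4000 - 1000

# U-Net layer shapes for a given base channel count (3 levels, two 3x3
# convolutions per level, skip concatenations, linear 1x1 head)
unet_shapes <- function(base) {
  cin <- c(1, base, base, 2 * base, 2 * base, 4 * base, 6 * base, 2 * base,
           3 * base, base, base)
  cout <- c(base, base, 2 * base, 2 * base, 4 * base, 4 * base, 2 * base,
            2 * base, base, base, 1)
  k <- c(rep(9, 10), 1)
  list(cin = cin, cout = cout, k = k)
}

# He-initialized weights; all randomness through R's RNG
unet_init <- function(base = 8, seed = 1) {
  sh <- unet_shapes(base)
  withr::with_seed(seed, {
    lapply(seq_along(sh$cin), function(i) {
      fan_in <- sh$cin[i] * sh$k[i]
      list(W = matrix(rnorm(sh$cout[i] * fan_in, sd = sqrt(2 / fan_in)),
                      sh$cout[i], fan_in),
           b = rep(0, sh$cout[i]))
    })
  })
}

#' Training configuration for the eFoV estimator
#'
#' Bundles the synthetic-corpus and optimization settings; a config plus
#' the seed fully determines a training run.
#'
#' @param n_pairs Number of training pairs (>= 8).
#' @param seed Integer seed driving corpus generation and training.
#' @param geometry Scan geometry used to simulate the corpus (default: a
#'   reduced desk-scale sampling of the same scanner: 144 angles, 4 mm
#'   channels).
#' @param recon_matrix Intermediate matrix for
#'   [prepare_network_input()] during corpus generation.
#' @param net_size Internal network resolution (the 256 x 256 estimator
#'   interface is down/up-sampled to this grid).
#' @param base_channels U-Net base channel count.
#' @param leaky_slope Leaky-ReLU negative slope.
#' @param learning_rate,batch_size,epochs ADAM settings.
#' @param val_fraction Fraction of pairs held out for validation
#'   (in (0, 0.5]).
#' @param checkpoint_path Optional path; the best-validation estimator is
#'   saved there with [save_estimator()].
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_pairs = 500, seed = 1,
                            geometry = scan_geometry(n_channels = 252,
                                                     channel_spacing_mm = 4,
                                                     n_angles = 144),
                            recon_matrix = 256, net_size = 64,
                            base_channels = 8, leaky_slope = 0.01,
                            learning_rate = 1e-3, batch_size = 10,
                            epochs = 30, val_fraction = 0.2,
                            checkpoint_path = NULL) {
  stopifnot(n_pairs >= 8, val_fraction > 0, val_fraction <= 0.5,
            net_size %% 4 == 0, 256 %% net_size == 0,
            recon_matrix %% 256 == 0)
  cfg <- list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
              geometry = geometry, recon_matrix = recon_matrix,
              net_size = as.integer(net_size),
              base_channels = as.integer(base_channels),
              leaky_slope = leaky_slope, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), val_fraction = val_fraction,
              checkpoint_path = checkpoint_path)
  class(cfg) <- "training_config"
  cfg
}

# stack corpus pair images into a net_size^2 x n array (normalized)
corpus_to_array <- function(corpus, which = c("input", "target"), net_size) {
  which <- match.arg(which)
  n <- length(corpus$pairs)
  out <- array(0, c(net_size, net_size, n))
  for (i in seq_len(n)) {
    img <- corpus$pairs[[i]][[which]]
    if (dim(img$values)[1] != net_size) img <- downsample_image(img, net_size)
    out[, , i] <- normalize_hu(img$values[, , 1])
  }
  out
}

#' Train the eFoV U-Net estimator
#'
#' Optimizes a small U-Net (3 resolution levels, leaky-ReLU activations,
#' residual output) with the ADAM optimizer on the DSSIM loss between
#' network output and ground-truth images, both on the internal
#' `net_size` grid.  The run is deterministic given the config: weight
#' initialization, batch shuffling and the train/validation split are all
#' driven by `config$seed`.  The best-validation-epoch weights are
#' returned; training aborts if the loss turns non-finite.
#'
#' @param corpus A `training_corpus` from [generate_training_corpus()].
#' @param config A [training_config()].
#' @return A `trained` [new_estimator()] whose `meta` holds the per-epoch
#'   train/validation DSSIM log, the validation DSSIM of the untrained
#'   network, the best epoch, and the config.
#' @export
train_estimator <- function(corpus, config) {
  stopifnot(inherits(corpus, "training_corpus"),
            inherits(config, "training_config"))
  n <- length(corpus$pairs)
  if (n < 2) stop("corpus too small")
  ns <- config$net_size
  x <- corpus_to_array(corpus, "input", ns)
  y <- corpus_to_array(corpus, "target", ns)
  n_val <- max(1L, ceiling(config$val_fraction * n))
  idx_val <- (n - n_val + 1L):n
  idx_tr <- seq_len(n - n_val)

  w <- unet_init(config$base_channels, config$seed)
  slope <- config$leaky_slope
  val_loss <- function(w) {
    out <- .unet_forward(x[, , idx_val, drop = FALSE], w, slope)
    mean(vapply(seq_along(idx_val),
                function(i) .dssim(out[, , i], y[, , idx_val[i]]), 0))
  }
  untrained_val <- val_loss(w)

  m <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  log <- data.frame(epoch = integer(), train_dssim = numeric(),
                    val_dssim = numeric())
  best <- list(val = untrained_val, w = w, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- withr::with_seed(config$seed + ep, sample(idx_tr))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      res <- .unet_loss_grad(x[, , bi, drop = FALSE],
                             y[, , bi, drop = FALSE], w, slope)
      if (!is.finite(res$loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1L
      t <- t + 1L
      lr_t <- config$learning_rate * sqrt(1 - b2^t) / (1 - b1^t)
      for (li in seq_along(w)) {
        for (p in c("W", "b")) {
          g <- res$grads[[li]][[p]]
          m[[li]][[p]] <- b1 * m[[li]][[p]] + (1 - b1) * g
          v[[li]][[p]] <- b2 * v[[li]][[p]] + (1 - b2) * g^2
          w[[li]][[p]] <- w[[li]][[p]] -
            lr_t * m[[li]][[p]] / (sqrt(v[[li]][[p]]) + eps)
        }
      }
    }
    vl <- val_loss(w)
    log <- rbind(log, data.frame(epoch = ep, train_dssim = ep_loss / nb,
                                 val_dssim = vl))
    if (vl < best$val) best <- list(val = vl, w = w, epoch = ep)
  }
  est <- trained_estimator(best$w, config,
                           meta = list(log = log,
                                       untrained_val_dssim = untrained_val,
                                       best_val_dssim = best$val,
                                       best_epoch = best$epoch))
  if (!is.null(config$checkpoint_path))
    save_estimator(est, config$checkpoint_path)
  est
}

# wrap trained weights into the estimator interface: the 256^2 input is
# area-averaged to the internal grid, the network's residual correction is
# bilinearly upsampled and added back to the full-resolution input
trained_estimator <- function(weights, config, meta = list()) {
  ns <- config$net_size
  slope <- config$leaky_slope
  fn <- function(img) {
    small <- if (dim(img$values)[1] == ns) img else downsample_image(img, ns)
    nsl <- n_slices(img)
    xin <- array(normalize_hu(small$values), c(ns, ns, nsl))
    out <- .unet_forward(xin, weights, slope)
    res <- img
    for (k in seq_len(nsl)) {
      corr <- out[, , k] - xin[, , k]
      res$values[, , k] <- img$values[, , k] +
        4000 * upsample_bilinear(corr, dim(img$values)[1])
    }
    res
  }
  new_estimator("trained", fn,
                meta = c(meta, list(weights = weights, config = config)))
}

# bilinear upsampling of a square matrix to size n_out (cell-centred)
upsample_bilinear <- function(m, n_out) {
  n_in <- nrow(m)
  if (n_in == n_out) return(m)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmin(pmax(floor(pos), 0), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  wi <- pos - i0
  a <- m[i0 + 1, , drop = FALSE] * (1 - wi) + m[i1 + 1, , drop = FALSE] * wi
  a[, i0 + 1, drop = FALSE] * rep(1 - wi, each = n_out) +
    a[, i1 + 1, drop = FALSE] * rep(wi, each = n_out)
}

#' Save / load a trained estimator
#'
#' The checkpoint is the package's native serialized form (weights,
#' config and training log plus a format tag).
#'
#' @param estimator A `trained` estimator.
#' @param path Checkpoint file path.
#' @return `load_estimator` returns the restored estimator.
#' @export
save_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "efov_estimator"),
            estimator$kind == "trained")
  obj <- list(format = "efovct_estimator", version = 1L,
              weights = estimator$meta$weights,
              config = estimator$meta$config,
              meta = estimator$meta[setdiff(names(estimator$meta),
                                            c("weights", "config"))])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "efovct_estimator"))
    stop("not an efovct estimator checkpoint")
  trained_estimator(obj$weights, obj$config, obj$meta)
}
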