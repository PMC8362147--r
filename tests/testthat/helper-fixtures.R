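# Shared fixtures and independent brute-force oracles.

# fast geometry for unit tests: same scanner distances and sFoV, coarse
# detector (8 mm channels) and 96 views
small_geometry <- function(n_angles = 96) {
  scan_geometry(n_channels = 126, channel_spacing_mm = 8,
                n_angles = n_angles)
}

# centered disc image (HU) on an 800 mm grid
disc_image <- function(radius_mm, hu = 0, matrix = 256, fov_mm = 800,
                       center = c(0, 0)) {
  sp <- fov_mm / matrix
  xs <- (seq_len(matrix) - (matrix + 1) / 2) * sp
  vals <- outer(xs, xs, function(x, y)
    ifelse((x - center[1])^2 + (y - center[2])^2 <= radius_mm^2, hu, -1000))
  ct_image(vals, sp)
}

disc_mask <- function(radius_mm, matrix = 256, fov_mm = 800,
                      center = c(0, 0)) {
  sp <- fov_mm / matrix
  xs <- (seq_len(matrix) - (matrix + 1) / 2) * sp
  m <- list(values = array(outer(xs, xs, function(x, y)
    (x - center[1])^2 + (y - center[2])^2 <= radius_mm^2),
    c(matrix, matrix, 1L)),
    pixel_spacing_mm = sp, slice_thickness_mm = 3, origin = c(0, 0))
  class(m) <- c("ct_mask", "ct_image")
  m
}

# wrap a logical matrix as a ct_mask on an 800 mm grid
as_test_mask <- function(m, fov_mm = 800) {
  n <- nrow(m)
  out <- list(values = array(m, c(n, n, 1L)), pixel_spacing_mm = fov_mm / n,
              slice_thickness_mm = 3, origin = c(0, 0))
  class(out) <- c("ct_mask", "ct_image")
  out
}

# brute-force eFoV-restricted Jaccard by explicit pixel count
brute_jaccard_efov <- function(mask_a, mask_b, sfov_radius_mm) {
  n <- dim(mask_a$values)[1]
  sp <- mask_a$pixel_spacing_mm
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  inter <- 0L
  uni <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (xs[i]^2 + xs[j]^2 > sfov_radius_mm^2) {
      av <- mask_a$values[i, j, 1]
      bv <- mask_b$values[i, j, 1]
      if (av && bv) inter <- inter + 1L
      if (av || bv) uni <- uni + 1L
    }
  }
  if (uni == 0L) 1 else inter / uni
}

# brute-force DSSIM: explicit windowed statistics with an 11x11 Gaussian
# (sigma 1.5) and periodic boundary, matching the documented definition
brute_dssim <- function(a, b) {
  n <- nrow(a)
  m <- ncol(a)
  g1 <- exp(-(-5:5)^2 / (2 * 1.5^2))
  g <- outer(g1, g1)
  g <- g / sum(g)
  c1 <- 1e-4
  c2 <- 9e-4
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ii <- ((i - 1) + (-5:5)) %% n + 1
    jj <- ((j - 1) + (-5:5)) %% m + 1
    wa <- a[ii, jj]
    wb <- b[ii, jj]
    mx <- sum(g * wa)
    my <- sum(g * wb)
    vx <- sum(g * wa^2) - mx^2
    vy <- sum(g * wb^2) - my^2
    cxy <- sum(g * wa * wb) - mx * my
    acc <- acc + ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  0.5 * (1 - acc / (n * m))
}
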