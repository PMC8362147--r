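test_that("DSSIM satisfies its metric identities", {
  set.seed(4)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- matrix(runif(32 * 32), 32, 32)
  expect_equal(dssim(x, x), 0)
  expect_equal(dssim(x, y), dssim(y, x), tolerance = 1e-12)
  expect_gte(dssim(x, y), 0)
  expect_lte(dssim(x, y), 1)
  # constant images: boundary-independent closed form
  # SSIM(0, 1) = C1 / (1 + C1) with C1 = 1e-4
  expect_equal(dssim(matrix(0, 32, 32), matrix(1, 32, 32)),
               0.5 * (1 - 1e-4 / (1 + 1e-4)), tolerance = 1e-9)
  expect_error(dssim(x, matrix(0, 16, 16)), "mismatch")
})

test_that("DSSIM matches the brute-force windowed-statistics oracle", {
  set.seed(11)
  for (trial in 1:3) {
    a <- matrix(runif(24 * 24), 24, 24)
    b <- a + matrix(rnorm(24 * 24, sd = 0.1), 24, 24)
    expect_equal(dssim(a, b), brute_dssim(a, b), tolerance = 1e-6)
  }
})

test_that("the DSSIM gradient matches central finite differences", {
  set.seed(5)
  x <- matrix(runif(24 * 24), 24, 24)
  y <- matrix(runif(24 * 24), 24, 24)
  gr <- efovct:::.dssim_grad(x, y)
  eps <- 1e-5
  for (idx in c(1L, 100L, 301L, 576L)) {
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    fd <- (efovct:::.dssim(xp, y) - efovct:::.dssim(xm, y)) / (2 * eps)
    expect_equal(gr[idx], fd, tolerance = 1e-6)
  }
})

test_that("U-Net loss gradients match finite differences (smooth regime)", {
  set.seed(7)
  w <- efovct:::unet_init(4, 3)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  y <- array(runif(32 * 32 * 2), c(32, 32, 2))
  r <- efovct:::.unet_loss_grad(x, y, w, 1.0)   # slope 1: no kinks
  eps <- 1e-6
  for (li in c(1L, 5L, 7L, 11L)) {
    w2 <- w
    w2[[li]]$W[1, 1] <- w2[[li]]$W[1, 1] + eps
    fd <- (efovct:::.unet_loss_grad(x, y, w2, 1.0)$loss - r$loss) / eps
    expect_equal(r$grads[[li]]$W[1, 1], fd, tolerance = 1e-4)
  }
})

test_that("training-pair generation is deterministic and truncated", {
  cfg <- training_config(n_pairs = 8, seed = 99)
  p1 <- corpus_pair(cfg, 3, with_sinogram = TRUE)
  p2 <- corpus_pair(cfg, 3, with_sinogram = TRUE)
  expect_identical(p1$input$values, p2$input$values)
  expect_identical(p1$target$values, p2$target$values)
  expect_identical(p1$spec$components, p2$spec$components)

  for (i in 1:4) {
    p <- corpus_pair(cfg, i, with_sinogram = TRUE)
    # body fits the bore ...
    co <- p$spec$components[1, ]
    expect_lte(sqrt(co$cx^2 + co$cy^2) + max(co$ax, co$ay), 400)
    # ... and exceeds the sFoV, so the scan is truncated
    expect_lt(min(projection_mass(p$sinogram)$normalized), 1)
  }
})

test_that("a one-epoch run on a tiny corpus trains and reproduces", {
  cfg <- training_config(n_pairs = 8, seed = 5, epochs = 1, net_size = 32,
                         batch_size = 4)
  corp <- generate_training_corpus(cfg)
  est <- train_estimator(corp, cfg)
  expect_s3_class(est, "efov_estimator")
  expect_equal(est$kind, "trained")
  expect_true(all(is.finite(est$meta$log$train_dssim)))
  expect_true(all(is.finite(est$meta$log$val_dssim)))
  # trained estimator honours the interface contract
  out <- apply_estimator(est, corp$pairs[[1]]$input)
  expect_equal(dim(out$values), c(256L, 256L, 1L))
  # bitwise reproducibility from (seed, config)
  est2 <- train_estimator(corp, cfg)
  expect_identical(est$meta$log, est2$meta$log)
})

test_that("estimator checkpoints round-trip through save/load", {
  cfg <- training_config(n_pairs = 8, seed = 5, epochs = 1, net_size = 32,
                         batch_size = 4)
  corp <- generate_training_corpus(cfg)
  est <- train_estimator(corp, cfg)
  path <- tempfile(fileext = ".rds")
  save_estimator(est, path)
  est2 <- load_estimator(path)
  out1 <- apply_estimator(est, corp$pairs[[2]]$input)
  out2 <- apply_estimator(est2, corp$pairs[[2]]$input)
  expect_identical(out1$values, out2$values)
})
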