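test_that("target expansion duplicates the blue channel and round-trips", {
  set.seed(2)
  rgb <- rgb_image(array(runif(8 * 8 * 3), c(8, 8, 3)))
  e3 <- expand_target_channels(rgb, 3)
  expect_identical(e3, rgb$values)
  e5 <- expand_target_channels(rgb, 5)
  expect_equal(dim(e5)[3], 5L)
  expect_identical(e5[, , 1:3], rgb$values)
  expect_identical(e5[, , 4], rgb$values[, , 3])
  expect_identical(e5[, , 5], rgb$values[, , 3])
  # expand then discard restores the RGB image bit-exactly
  expect_identical(discard_surplus_channels(e5)$values, rgb$values)
  expect_error(expand_target_channels(rgb, 2), "RGB")
})

test_that("surplus-channel discarding keeps the first three and clips", {
  set.seed(3)
  x6 <- array(runif(6 * 6 * 6, -0.5, 1.5), c(6, 6, 6))
  out <- discard_surplus_channels(x6)
  expect_equal(dim(out$values), c(6, 6, 3))
  expect_true(all(out$values >= 0 & out$values <= 1))
  inside <- x6[, , 1:3] >= 0 & x6[, , 1:3] <= 1
  expect_identical(out$values[inside], x6[, , 1:3][inside])
  # idempotent once in range
  expect_identical(discard_surplus_channels(out$values)$values, out$values)
  expect_error(discard_surplus_channels(array(0, c(4, 4, 2))), "3 channels")
})

test_that("learning-rate schedule follows the stepped linear closed form", {
  cfg <- mcgan_config(n_channels = 3, patch_size = 32, max_epochs = 20,
                      lr = 1e-3, lr_decay_interval = 5,
                      downsampling_depth = 2)
  # half = 10, two decay steps of 5 epochs: full, half, zero
  expect_equal(sapply(1:20, lr_at_epoch, cfg = cfg),
               c(rep(1e-3, 10), rep(5e-4, 5), rep(0, 5)))
  cfg2 <- mcgan_config(n_channels = 3, patch_size = 256, max_epochs = 200)
  expect_equal(lr_at_epoch(1, cfg2), 2e-4)
  expect_equal(lr_at_epoch(100, cfg2), 2e-4)
  expect_equal(lr_at_epoch(101, cfg2), 2e-4 * 0.9)
  expect_equal(lr_at_epoch(200, cfg2), 0)
})

test_that("model construction is seeded and shape-correct", {
  cfg <- mcgan_config(n_channels = 4, patch_size = 64, seed = 11,
                      downsampling_depth = 4, filters = 4,
                      disc_filters = 4)
  b1 <- build_models(cfg)
  b2 <- build_models(cfg)
  expect_identical(b1$params, b2$params)
  cfg3 <- cfg; cfg3$seed <- 12L
  expect_false(identical(build_models(cfg3)$params$gAB$enc1_W,
                         b1$params$gAB$enc1_W))
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  y <- generate(b1, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))
  # PatchGAN head emits a spatial logit map, not a scalar
  d <- parsstain:::disc_fwd(b1$params$dB, x, b1$d_arch)
  expect_gt(prod(dim(d$y)[1:2]), 1)
  expect_error(mcgan_config(n_channels = 3, patch_size = 60,
                            downsampling_depth = 3), "multiple")
})

test_that("backpropagation matches central finite differences", {
  arch <- parsstain:::unet_arch(3L, 3L, 2L, 4L, 16L)
  p <- parsstain:::with_seed(1, parsstain:::unet_init(arch))
  set.seed(42)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  tgt <- array(runif(16 * 16 * 3), c(16, 16, 3))
  loss <- function(p) mean((parsstain:::unet_fwd(p, x, arch)$y - tgt)^2)
  fw <- parsstain:::unet_fwd(p, x, arch)
  bw <- parsstain:::unet_bwd(p, fw$cache, 2 * (fw$y - tgt) / length(tgt),
                             arch)
  eps <- 1e-5
  for (nm in names(p)) {
    set.seed(nchar(nm) * 13)
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss(pp)
    num <- (up - dn) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
  # gradient w.r.t. the input (needed for chained generator updates)
  i <- 101
  x2 <- x; x2[i] <- x2[i] + eps
  up <- mean((parsstain:::unet_fwd(p, x2, arch)$y - tgt)^2)
  x2[i] <- x2[i] - 2 * eps
  dn <- mean((parsstain:::unet_fwd(p, x2, arch)$y - tgt)^2)
  expect_equal(bw$dx[i], (up - dn) / (2 * eps), tolerance = 1e-4)

  darch <- parsstain:::disc_arch(3L, 4L, 16L)
  pd <- parsstain:::with_seed(2, parsstain:::disc_init(darch))
  dloss <- function(pd) mean((parsstain:::disc_fwd(pd, x, darch)$y - 1)^2)
  fd <- parsstain:::disc_fwd(pd, x, darch)
  bd <- parsstain:::disc_bwd(pd, fd$cache, 2 * (fd$y - 1) / length(fd$y),
                             darch)
  for (nm in c("l1_W", "l2_W", "l2_g", "l3_W", "l3_b")) {
    set.seed(nchar(nm) * 5)
    i <- sample(length(pd[[nm]]), 1)
    pp <- pd; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- dloss(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- dloss(pp)
    expect_equal(bd$grads[[nm]][i], (up - dn) / (2 * eps),
                 tolerance = 1e-4, label = paste("disc grad", nm))
  }
})

test_that("a short training run keeps finite books and reproduces", {
  pairs <- toy_pairs(n_pairs = 4, size = 32, n_channels = 3, seed = 6)
  cfg <- mcgan_config(n_channels = 3, patch_size = 32, max_epochs = 2,
                      downsampling_depth = 2, filters = 4,
                      disc_filters = 4, seed = 5)
  b <- mcgan_train(pairs, cfg)
  expect_equal(nrow(b$history), 2)
  expect_true(all(is.finite(as.matrix(b$history))))
  expect_true(all(c("loss_g", "loss_adv", "loss_cyc", "loss_idt",
                    "loss_pair", "loss_d") %in% names(b$history)))
  b2 <- mcgan_train(pairs, cfg)
  expect_identical(b$history, b2$history)
  expect_identical(b$params$gAB$enc1_W, b2$params$gAB$enc1_W)
  expect_error(mcgan_train(pairs,
                           mcgan_config(n_channels = 5, patch_size = 32,
                                        downsampling_depth = 2)),
               "channel-count mismatch")
})

test_that("training on a self-colorization task reduces the cycle loss", {
  # truth is a deterministic function of the input channels, so a few
  # epochs must beat the untrained epoch-1 cycle loss
  pairs <- toy_pairs(n_pairs = 6, size = 32, n_channels = 3, seed = 8)
  cfg <- mcgan_config(n_channels = 3, patch_size = 32, max_epochs = 5,
                      downsampling_depth = 2, filters = 4,
                      disc_filters = 4, seed = 2)
  b <- mcgan_train(pairs, cfg)
  expect_lt(tail(b$history$loss_cyc, 1), b$history$loss_cyc[1])
  expect_lt(tail(b$history$loss_pair, 1), b$history$loss_pair[1])
})

test_that("patch grids cover the image with clamped borders", {
  g <- patch_grid(100, 70, 32, 16)
  expect_true(all(g$coords$row + 31 <= 100))
  expect_true(all(g$coords$col + 31 <= 70))
  expect_true((100 - 32 + 1) %in% g$coords$row)
  expect_true((70 - 32 + 1) %in% g$coords$col)
  den <- blend_weight_map(g, 100, 70)
  expect_true(all(den > 0))
  expect_error(patch_grid(20, 20, 32, 16), "larger")
})

test_that("blended inference matches direct and oracle computations", {
  set.seed(9)
  chans <- lapply(1:3, function(i)
    channel_image(matrix(runif(32 * 32), 32, 32), paste0("c", i)))
  stack <- channel_stack(chans)
  # single patch covering the whole image: no blending at all
  stub <- function(x) clamp01(x + 0.1)
  g1 <- patch_grid(32, 32, 32, 32)
  out1 <- colorize(NULL, stack, grid = g1, generator = stub)
  direct <- discard_surplus_channels(stub(stack_to_array(stack)))$values
  dimnames(direct) <- NULL
  expect_equal(out1$values, direct)
  # constant generator: blending conserves constants at any overlap
  cst <- function(x) array(0.37, dim(x))
  g2 <- patch_grid(32, 32, 16, 8)
  out2 <- colorize(NULL, stack, grid = g2, generator = cst)
  expect_equal(out2$values, array(0.37, c(32, 32, 3)), tolerance = 1e-12)
  # patch-dependent bias vs a brute-force weighted-accumulation oracle
  counter <- local({ i <- 0; function(x) { i <<- i + 1
    array(clamp01(0.2 + 0.01 * i), dim(x)) } })
  g3 <- patch_grid(32, 32, 16, 8)
  out3 <- colorize(NULL, stack, grid = g3, generator = counter)
  wt <- parsstain:::patch_tent(16)
  num <- array(0, c(32, 32, 3)); den <- matrix(0, 32, 32)
  for (k in seq_len(nrow(g3$coords))) {
    ys <- g3$coords$row[k] + 0:15; xs <- g3$coords$col[k] + 0:15
    for (ch in 1:3) num[ys, xs, ch] <- num[ys, xs, ch] + (0.2 + 0.01 * k) * wt
    den[ys, xs] <- den[ys, xs] + wt
  }
  for (ch in 1:3) num[, , ch] <- num[, , ch] / den
  expect_equal(out3$values, num, tolerance = 1e-12)
})

test_that("model checkpoints round-trip through disk", {
  pairs <- toy_pairs(n_pairs = 2, size = 16, n_channels = 3, seed = 3)
  cfg <- mcgan_config(n_channels = 3, patch_size = 16, max_epochs = 1,
                      downsampling_depth = 2, filters = 4,
                      disc_filters = 4, seed = 4)
  b <- mcgan_train(pairs, cfg)
  base <- file.path(withr::local_tempdir(), "ckpt")
  save_model_bundle(b, base)
  b2 <- load_model_bundle(base)
  expect_identical(b2$params, b$params)
  expect_equal(b2$history, b$history)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(generate(b2, x), generate(b, x))
})
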