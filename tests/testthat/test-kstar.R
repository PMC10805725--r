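test_that("angular distance is zero on rays, one on orthogonal signals", {
  x <- c(1, 2, -3)
  expect_equal(angular_distance(x, x), 0)
  expect_equal(angular_distance(x, -x), 0)
  expect_equal(angular_distance(x, 2 * x), 0)
  expect_equal(angular_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(angular_distance(c(1, 0), c(1, 1)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(angular_distance(c(1, 0), c(1, 1)),
               angular_distance(c(1, 1), c(1, 0)))
  expect_error(angular_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("angular distance is invariant to scaling either argument", {
  for (seed in 1:20) {
    parsstain:::with_seed(seed, {
      x <- rnorm(12); y <- rnorm(12)
      a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
      b <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
      expect_equal(angular_distance(a * x, b * y), angular_distance(x, y),
                   tolerance = 1e-12)
    })
  }
})

test_that("centroid update matches the scatter-matrix eigenvector", {
  # rank-1 cluster: centroid is the shared direction
  v <- c(3, -1, 2)
  members <- rbind(2 * v, -0.5 * v, v)
  cen <- update_centroid(members)
  expect_equal(angular_distance(cen, v), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(cen^2)), 1, tolerance = 1e-12)

  # documented 2x2 case: leading eigenvector of [[5, 1], [1, 1]]
  m <- rbind(c(2, 0), c(1, 1))
  ev <- eigen(t(m) %*% m, symmetric = TRUE)$vectors[, 1]
  expect_equal(angular_distance(update_centroid(m), ev), 0,
               tolerance = 1e-10)

  # invariant to negating any subset of members
  parsstain:::with_seed(3, {
    mm <- matrix(rnorm(40), 8, 5)
    flip <- sample(c(-1, 1), 8, TRUE)
    expect_equal(update_centroid(mm), update_centroid(flip * mm),
                 tolerance = 1e-10)
  })
  expect_error(update_centroid(matrix(0, 3, 4)), "non-zero")
})

test_that("K*-means recovers orthogonal shape families exactly", {
  shapes <- diag(2)[, 1:2]
  sig <- scaled_family_signals(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)),
                               per_shape = 25)
  res <- kstar_cluster(sig, K = 2, seed = 1)
  mm <- match_features(res$feature_set$feature_matrix,
                       t(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))))
  expect_lt(max(mm$distances), 1e-6)
  expect_true(all(res$assignment$distance >= 0 &
                    res$assignment$distance <= 1))
})

test_that("K*-means is deterministic for a fixed seed", {
  sig <- scaled_family_signals(rbind(c(1, 0.2, 0), c(0, 1, -0.3)),
                               per_shape = 20, noise = 0.05, seed = 2)
  a <- kstar_cluster(sig, K = 2, seed = 7)
  b <- kstar_cluster(sig, K = 2, seed = 7)
  expect_identical(a, b)
})

test_that("inertia is non-increasing within a run and drops with K", {
  shapes <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0),
                  c(0, 0, 0, 0, 1, 0))
  sig <- scaled_family_signals(shapes, per_shape = 20, noise = 0.15,
                               seed = 5)
  r2 <- kstar_cluster(sig, K = 2, seed = 1)
  r3 <- kstar_cluster(sig, K = 3, seed = 1)
  expect_true(all(diff(r2$assignment$inertia) <= 1e-9))
  expect_true(all(diff(r3$assignment$inertia) <= 1e-9))
  expect_gt(r2$feature_set$meta$inertia, r3$feature_set$meta$inertia)
})

test_that("unmixing inverts an exact linear synthesis", {
  parsstain:::with_seed(6, {
    n <- 12; K <- 3
    fmat <- qr.Q(qr(matrix(rnorm(n * K), n, K)))
    fmat <- apply(fmat, 2, parsstain:::sign_normalize)
    fs <- feature_set(fmat, meta = list(window = c(0, n)))
    w_true <- matrix(runif(6 * K, 0.5, 2), 6, K)
    sig <- w_true %*% t(fmat)
    r <- td_signal_raster(array(sig, c(2, 3, n)), 1,
                          data.frame(label = "EX266", time_ns = 0))
    fi <- unmix(r, fs)
    amps <- sapply(fi$images, function(im) as.vector(im$values))
    expect_equal(unname(amps), unname(w_true), tolerance = 1e-10)
  })
  # zero signal -> zero amplitudes
  fs0 <- feature_set(apply(qr.Q(qr(matrix(c(1, 3, 2, 8, 5, 1, 9, 4), 4, 2))), 2,
                           parsstain:::sign_normalize),
                     meta = list(window = c(0, 4)))
  r0 <- td_signal_raster(array(0, c(1, 2, 4)), 1,
                         data.frame(label = "EX266", time_ns = 0))
  expect_true(all(sapply(unmix(r0, fs0)$images,
                         function(im) all(im$values == 0))))
})

test_that("unmixing of noisy signals equals the normal-equations solution", {
  parsstain:::with_seed(8, {
    n <- 10; K <- 2
    fmat <- matrix(rnorm(n * K), n, K)
    fmat <- apply(fmat, 2, function(v)
      parsstain:::sign_normalize(v / sqrt(sum(v^2))))
    fs <- feature_set(fmat, meta = list(window = c(0, n)))
    sig <- matrix(rnorm(8 * n), 8, n)
    r <- td_signal_raster(array(sig, c(2, 4, n)), 1,
                          data.frame(label = "EX266", time_ns = 0))
    fi <- unmix(r, fs)
    oracle <- t(solve(crossprod(fmat), t(fmat) %*% t(sig)))
    amps <- sapply(fi$images, function(im) as.vector(im$values))
    expect_equal(unname(amps), unname(oracle), tolerance = 1e-9)
  })
})

test_that("rank-deficient feature matrices are rejected with a culprit", {
  v <- c(1, 2, 3, 4) / sqrt(30)
  fmat <- cbind(v, v + 1e-14)
  fmat <- apply(fmat, 2, function(x)
    parsstain:::sign_normalize(x / sqrt(sum(x^2))))
  fs <- feature_set(fmat, meta = list(window = c(0, 4)))
  r <- td_signal_raster(array(1, c(1, 1, 4)), 1,
                        data.frame(label = "EX266", time_ns = 0))
  expect_error(unmix(r, fs), "near-collinear")
})

test_that("full-subset learning reproduces clustering on all usable pixels", {
  sp <- phantom_spec(height = 24, width = 24, tissue = "brain", seed = 4,
                     noise_sd = 0)
  ph <- generate_phantom(sp)
  fs_full <- learn_features(ph$nr_raster, K = 2, subset_fraction = 1,
                            seed = 3)
  win <- time_window(fs_full$meta$window[1], fs_full$meta$window[2])
  s <- parsstain:::windowed_signals(ph$nr_raster, win)
  s <- s[filter_dead_pixels(s), , drop = FALSE]
  direct <- kstar_cluster(s, K = 2, seed = 3)
  expect_equal(fs_full$feature_matrix, direct$feature_set$feature_matrix)
})

test_that("learned features recover the phantom basis and are seed-stable", {
  sp <- phantom_spec(height = 64, width = 64, tissue = "skin", seed = 12)
  ph <- generate_phantom(sp)
  first <- parsstain:::sample_at_or_after(sp$schedule$time_ns[1],
                                          sp$time_step_ns)
  basis_w <- ph$truth$basis[(first + 1):sp$n_samples, ]
  fs1 <- learn_features(ph$nr_raster, K = 3, subset_fraction = 0.3,
                        seed = 1)
  mm <- match_features(fs1$feature_matrix, basis_w)
  expect_lt(max(mm$distances), 0.05)
  # a different learning seed lands on the same basis up to permutation
  fs2 <- learn_features(ph$nr_raster, K = 3, subset_fraction = 0.3,
                        seed = 99)
  cross <- match_features(fs2$feature_matrix, fs1$feature_matrix)
  expect_lt(max(cross$distances), 0.05)
})

test_that("feature sets survive a serialization round trip exactly", {
  sig <- scaled_family_signals(rbind(c(1, 0, 0.1), c(0.1, 1, 0)),
                               per_shape = 15, seed = 9)
  fs <- kstar_cluster(sig, K = 2, seed = 1)$feature_set
  fs$meta$window <- c(0L, 3L)
  base <- file.path(withr::local_tempdir(), "fs")
  write_feature_set(fs, base)
  back <- read_feature_set(base)
  expect_identical(back$feature_matrix, fs$feature_matrix)
  expect_equal(back$K, fs$K)
  expect_equal(back$meta$inertia, fs$meta$inertia)
})
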