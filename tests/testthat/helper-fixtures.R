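# Tiny deterministic fixtures shared across test files; everything is built
# in code (no data files).

# raster with a single pixel whose trace is `values`; pre-excitation samples
# (before `event_ns`) default to zero so the baseline is zero
pixel_raster <- function(values, dt = 1, event_ns = 0,
                         label = "EX266", pre = NULL) {
  if (!is.null(pre)) values <- c(pre, values)
  td_signal_raster(array(values, c(1, 1, length(values))), dt,
                   data.frame(label = label, time_ns = event_ns))
}

# H x W raster with identical traces at every pixel
uniform_raster <- function(trace, h = 2, w = 2, dt = 1, event_ns = 0) {
  sig <- array(rep(trace, each = h * w), c(h, w, length(trace)))
  td_signal_raster(sig, dt, data.frame(label = "EX266", time_ns = event_ns))
}

# signals drawn as random positive/negative scalings of given unit shapes
# (rows of `shapes`), optionally with additive noise
scaled_family_signals <- function(shapes, per_shape = 30, noise = 0,
                                  seed = 1) {
  parsstain:::with_seed(seed, {
    out <- NULL
    for (k in seq_len(nrow(shapes))) {
      sc <- runif(per_shape, 0.5, 2) * sample(c(-1, 1), per_shape, TRUE)
      block <- outer(sc, shapes[k, ])
      if (noise > 0)
        block <- block + matrix(rnorm(length(block), sd = noise),
                                nrow(block), ncol(block))
      out <- rbind(out, block)
    }
    out
  })
}

# small registered pairs with a simple linear channel->color relationship
toy_pairs <- function(n_pairs = 4, size = 32L, n_channels = 3L, seed = 1) {
  parsstain:::with_seed(seed, lapply(seq_len(n_pairs), function(i) {
    chans <- lapply(seq_len(n_channels), function(ci)
      channel_image(matrix(runif(size * size), size, size),
                    paste0("ch", ci)))
    stack <- channel_stack(chans)
    arr <- stack_to_array(stack)
    truth <- rgb_image(clamp01(array(c(arr[, , 1], 1 - arr[, , 1],
                                       arr[, , min(2, n_channels)]),
                                     c(size, size, 3))))
    registered_pair(stack, truth)
  }))
}

clamp01 <- function(v) {
  v[v < 0] <- 0
  v[v > 1] <- 1
  v
}

# brute-force dense 2-D convolution with reflected edges (oracle for
# gaussian_blur)
dense_blur_oracle <- function(m, sigma) {
  r <- min(as.integer(ceiling(3 * sigma)), nrow(m) - 1L, ncol(m) - 1L)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  reflect <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k2[di + r + 1, dj + r + 1] *
        m[reflect(i + di, nrow(m)), reflect(j + dj, ncol(m))]
    out[i, j] <- acc
  }
  out
}
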