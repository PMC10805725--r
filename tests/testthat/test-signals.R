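test_that("excitation windows honor the half-open boundary convention", {
  r <- td_signal_raster(array(0, c(1, 1, 1000)), 1,
                        data.frame(label = c("EX266", "EX532"),
                                   time_ns = c(0, 500)))
  w <- split_excitation_windows(r, guard_ns = 0)
  expect_equal(c(w$EX266$start_index, w$EX266$end_index), c(0, 500))
  expect_equal(c(w$EX532$start_index, w$EX532$end_index), c(500, 1000))

  single <- td_signal_raster(array(0, c(1, 1, 200)), 1,
                             data.frame(label = "EX266", time_ns = 0))
  w1 <- split_excitation_windows(single)
  expect_equal(c(w1$EX266$start_index, w1$EX266$end_index), c(0, 200))
})

test_that("guarded window indices match a brute-force sample scan", {
  r <- td_signal_raster(array(0, c(1, 1, 500)), 2,
                        data.frame(label = c("EX266", "EX532"),
                                   time_ns = c(0, 500)))
  w <- split_excitation_windows(r, guard_ns = 10)
  # oracle: first 0-based sample index whose time >= t + guard
  scan <- function(t) which((0:499) * 2 >= t)[1] - 1L
  expect_equal(w$EX266$start_index, scan(0 + 10))
  expect_equal(w$EX266$end_index, scan(500))
  expect_equal(w$EX532$start_index, scan(500 + 10))
  expect_equal(w$EX532$end_index, 500L)
  expect_error(split_excitation_windows(r, guard_ns = 600), "unseparable")
})

test_that("guard-free windows tile the post-excitation samples", {
  for (seed in 1:5) {
    r <- parsstain:::with_seed(seed, {
      n <- sample(50:200, 1)
      dt <- runif(1, 0.5, 4)
      t1 <- runif(1, 0, n * dt / 4)
      t2 <- t1 + runif(1, n * dt / 4, n * dt / 2)
      td_signal_raster(array(0, c(1, 1, n)), dt,
                       data.frame(label = c("EX266", "EX532"),
                                  time_ns = c(t1, min(t2, (n - 1) * dt))))
    })
    w <- split_excitation_windows(r, guard_ns = 0)
    covered <- unlist(lapply(unname(w), function(win)
      win$start_index:(win$end_index - 1L)))
    expect_equal(sort(covered), w[[1]]$start_index:(r$n_samples - 1L))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("NR integral is the baseline-relative modulation energy", {
  # zero signal, zero energy
  z <- uniform_raster(rep(0, 16))
  expect_equal(extract_nr_integral(z, time_window(0, 16))$values,
               matrix(0, 2, 2))
  # single pixel, baseline 0, window [3, -4], dt = 1 -> 9 + 16 = 25
  r <- pixel_raster(c(3, -4))
  expect_equal(extract_nr_integral(r, time_window(0, 2))$values[1, 1], 25)
  # constant signal equals its baseline -> zero energy
  cst <- pixel_raster(rep(7, 20), event_ns = 10)
  expect_equal(extract_nr_integral(cst, time_window(10, 20))$values[1, 1], 0)
  # abs-deviation variant: |3| + |-4| = 7
  expect_equal(extract_nr_integral(r, time_window(0, 2),
                                   energy = "abs")$values[1, 1], 7)
  # time_step scales the integral
  r2 <- pixel_raster(c(3, -4), dt = 2)
  expect_equal(extract_nr_integral(r2, time_window(0, 2))$values[1, 1], 50)
})

test_that("NR integral is offset-invariant and scales quadratically", {
  base <- parsstain:::with_seed(11, rnorm(40))
  r <- pixel_raster(base, event_ns = 8, pre = rep(0, 8))
  w <- time_window(8, 48)
  e0 <- extract_nr_integral(r, w)$values[1, 1]
  # adding a constant to the whole trace moves the baseline with it
  r_off <- pixel_raster(base + 3.7, event_ns = 8, pre = rep(3.7, 8))
  expect_equal(extract_nr_integral(r_off, w)$values[1, 1], e0)
  # scaling the trace by alpha scales the energy by alpha^2
  r_sc <- pixel_raster(2.5 * base, event_ns = 8, pre = rep(0, 8))
  expect_equal(extract_nr_integral(r_sc, w)$values[1, 1], 2.5^2 * e0)
})

test_that("amplitude channel is the max absolute baseline deviation", {
  r <- pixel_raster(c(1, -5, 2))
  expect_equal(extract_amplitude(r, time_window(0, 3))$values[1, 1], 5)
  z <- uniform_raster(rep(0, 8))
  expect_equal(extract_amplitude(z, time_window(0, 8))$values,
               matrix(0, 2, 2))
  # baseline 2 from the pre-excitation samples, values [2, 2, 7] -> 5
  r2 <- pixel_raster(c(2, 2, 7), event_ns = 2, pre = c(2, 2))
  expect_equal(extract_amplitude(r2, time_window(2, 5))$values[1, 1], 5)
  # linear scaling
  base <- parsstain:::with_seed(4, rnorm(30))
  ra <- pixel_raster(base); rb <- pixel_raster(-3 * base)
  w <- time_window(0, 30)
  expect_equal(extract_amplitude(rb, w)$values[1, 1],
               3 * extract_amplitude(ra, w)$values[1, 1])
})

test_that("scatter baseline averages the pre-excitation detection", {
  r <- pixel_raster(c(4, 6, 9, 9), event_ns = 2)
  expect_equal(extract_scatter_baseline(r, time_window(0, 2))$values[1, 1], 5)
  r4 <- pixel_raster(c(1, 2, 3, 4, 8), event_ns = 4)
  expect_equal(extract_scatter_baseline(r4, time_window(0, 4))$values[1, 1],
               2.5)
  cst <- uniform_raster(rep(3.3, 10), event_ns = 5)
  expect_equal(extract_scatter_baseline(cst)$values, matrix(3.3, 2, 2))
  expect_error(extract_scatter_baseline(r, time_window(0, 3)), "overlaps")
})

test_that("preprocessing normalizes, saturates and reverses", {
  ramp <- channel_image(matrix(seq(0, 1, length.out = 100), 10, 10), "x")
  out <- preprocess_channel(ramp, saturation_fraction = 0, reverse = FALSE)
  expect_equal(out$values, ramp$values)
  # reversal is an involution
  rev1 <- preprocess_channel(ramp, saturation_fraction = 0)
  expect_equal(1 - rev1$values, ramp$values)
  # sort-based quantile oracle on a 1000-pixel ramp with 1% saturation
  v <- matrix(0:999, 40, 25)
  img <- channel_image(v, "ramp")
  out2 <- preprocess_channel(img, saturation_fraction = 0.01,
                             reverse = FALSE)
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  expect_true(all(out2$values[v <= q[1]] == 0))
  expect_true(all(out2$values[v >= q[2]] == 1))
  oracle <- (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  expect_equal(out2$values, oracle)
})

test_that("preprocessing is affine-invariant and bounded", {
  img <- channel_image(matrix(parsstain:::with_seed(5, rnorm(96)), 12, 8),
                       "x")
  a <- preprocess_channel(img)
  b <- preprocess_channel(channel_image(2.3 * img$values + 17, "x"))
  expect_equal(a$values, b$values)
  expect_true(all(a$values >= 0 & a$values <= 1))
  # degenerate contrast warns and returns the flat extreme
  expect_warning(
    flat <- preprocess_channel(channel_image(matrix(1, 4, 4), "x")),
    "constant")
  expect_equal(flat$values, matrix(1, 4, 4))
  expect_warning(
    flat0 <- preprocess_channel(channel_image(matrix(1, 4, 4), "x"),
                                reverse = FALSE))
  expect_equal(flat0$values, matrix(0, 4, 4))
})

test_that("raster and window validation reject malformed inputs", {
  expect_error(td_signal_raster(array(NA_real_, c(1, 1, 4)), 1,
                                data.frame(label = "EX266", time_ns = 0)),
               "finite")
  expect_error(td_signal_raster(array(0, c(1, 1, 4)), 1,
                                data.frame(label = c("EX532", "EX266"),
                                           time_ns = c(0, 2))),
               "must follow")
  expect_error(time_window(3, 3))
  expect_error(extract_nr_integral(pixel_raster(1:4), time_window(0, 9)),
               "past the end")
})
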