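#' Gaussian blur of a matrix or multi-channel array
#'
#' Separable Gaussian filter with kernel radius `ceiling(3 * sigma)` and
#' reflected (mirror) edge padding. `sigma = 0` returns the input unchanged.
#' Constants are preserved exactly (the kernel is normalized to sum 1).
#'
#' @param x numeric matrix or `H x W x C` array.
#' @param sigma standard deviation in pixels, `>= 0`.
#' @return blurred object of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    for (k in seq_len(dim(x)[3])) out[, , k] <- gaussian_blur(x[, , k], sigma)
    return(out)
  }
  blur_1d <- function(m) {
    # reflect-pad rows then convolve columns of m with a normalized kernel;
    # the radius is clamped so the mirror indices stay in range
    n <- nrow(m)
    r <- min(as.integer(ceiling(3 * sigma)), n - 1L)
    kern <- exp(-((-r:r)^2) / (2 * sigma^2))
    kern <- kern / sum(kern)
    pad_idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    mp <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(kern))
      out <- out + kern[t] * mp[(t - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(x))))
}
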