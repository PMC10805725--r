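#' Blur a prediction/truth pair before metric computation
#'
#' Registration between acquired and stained images is never pixel-perfect;
#' blurring both domains identically before computing pixel-wise metrics
#' suppresses the effect of small registration errors. `sigma = 0` is the
#' identity.
#'
#' @param pred,truth [rgb_image]s of equal dimensions.
#' @param sigma Gaussian standard deviation in pixels.
#' @return list with blurred `pred` and `truth`.
#' @export
blur_pair <- function(pred, truth, sigma) {
  stopifnot(inherits(pred, "rgb_image"), inherits(truth, "rgb_image"))
  if (pred$height != truth$height || pred$width != truth$width)
    stop("dimension mismatch between prediction and truth")
  if (sigma == 0) return(list(pred = pred, truth = truth))
  list(pred = rgb_image(clip01(gaussian_blur(pred$values, sigma))),
       truth = rgb_image(clip01(gaussian_blur(truth$values, sigma))))
}

rgb_to_luminance <- function(img) {
  v <- if (inherits(img, "rgb_image")) img$values else img
  0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
}

# separable "valid" correlation of a matrix with a 1-D kernel along both axes
win_filter <- function(m, kern) {
  r <- length(kern)
  f1 <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n - r + 1L, ncol(x))
    for (t in seq_len(r))
      out <- out + kern[t] * x[(t - 1L) + seq_len(n - r + 1L), , drop = FALSE]
    out
  }
  t(f1(t(f1(m))))
}

#' Structural similarity index of two grayscale images
#'
#' Windowed SSIM with the standard constants: 11 x 11 Gaussian window
#' (sigma 1.5), `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, population (moment)
#' window statistics, averaged over the valid (fully-windowed) region.
#'
#' @param x,y numeric matrices with values in `[0, data_range]`.
#' @param data_range dynamic range L (default 1).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim_index <- function(x, y, data_range = 1) {
  if (!all(dim(x) == dim(y))) stop("dimension mismatch")
  if (min(dim(x)) < 11L) stop("images must be at least 11 x 11 for SSIM")
  kern <- exp(-((-5:5)^2) / (2 * 1.5^2))
  kern <- kern / sum(kern)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- win_filter(x, kern); my <- win_filter(y, kern)
  sxx <- win_filter(x * x, kern) - mx^2
  syy <- win_filter(y * y, kern) - my^2
  sxy <- win_filter(x * y, kern) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Image-quality metrics between a colorization and its ground truth
#'
#' Blurs both images with [blur_pair()], then computes RMSE over all three
#' channels on the 0-255 intensity scale, `PSNR = 20 log10(255 / RMSE)` in
#' dB (flagged infinite when RMSE is 0), and SSIM on the
#' luminance-converted pair. An optional perceptual metric hook (`lpips_fn`)
#' may supply an LPIPS-style score; none ships with the package.
#'
#' @param pred,truth [rgb_image]s of equal dimensions.
#' @param sigma pre-metric blur in pixels (default 2).
#' @param lpips_fn optional `function(pred, truth) -> numeric` perceptual
#'   metric applied to the blurred pair.
#' @return a `metric_report`: list with `ssim`, `psnr_db`, `rmse`, `lpips`
#'   (NA unless `lpips_fn` given) and `blur_sigma`.
#' @export
compute_metrics <- function(pred, truth, sigma = 2, lpips_fn = NULL) {
  bp <- blur_pair(pred, truth, sigma)
  diff255 <- 255 * (bp$pred$values - bp$truth$values)
  rmse <- sqrt(mean(diff255^2))
  psnr <- if (rmse == 0) Inf else 20 * log10(255 / rmse)
  ssim <- ssim_index(rgb_to_luminance(bp$pred), rgb_to_luminance(bp$truth))
  lpips <- if (is.null(lpips_fn)) NA_real_ else lpips_fn(bp$pred, bp$truth)
  structure(list(ssim = ssim, psnr_db = psnr, rmse = rmse, lpips = lpips,
                 blur_sigma = sigma),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> SSIM %.4f | PSNR %.2f dB | RMSE %.2f%s (blur %.3g px)\n",
              x$ssim, x$psnr_db, x$rmse,
              if (is.na(x$lpips)) "" else sprintf(" | LPIPS %.3f", x$lpips),
              x$blur_sigma))
  invisible(x)
}

#' Enumerate all channel subsets for the combination study
#'
#' All `2^N - 1` non-empty subsets of the channel array (for
#' `min_size = 1`), in deterministic order: by subset size, then
#' lexicographically in the input channel order.
#'
#' @param channel_names unique channel names (N <= 12; the exhaustive search
#'   doubles per added channel).
#' @param min_size smallest subset size to keep (default 1).
#' @return list of character vectors.
#' @export
enumerate_combinations <- function(channel_names, min_size = 1L) {
  n <- length(channel_names)
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (n > 12L)
    stop("more than 12 channels: exhaustive search is impractical, use a heuristic subset search")
  out <- list()
  for (size in seq.int(min_size, n)) {
    idx <- utils::combn(n, size)
    for (j in seq_len(ncol(idx)))
      out[[length(out) + 1L]] <- channel_names[idx[, j]]
  }
  out
}
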