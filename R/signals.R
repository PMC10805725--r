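#' Conventional PARS channel extraction
#'
#' A raw PARS acquisition records, at every pixel, the time-resolved
#' non-radiative intensity modulation of the detection beam. Each excitation
#' event (266 nm, then 532 nm roughly 500 ns later) produces one modulation
#' peak. The conventional reductions of this trace are: the non-radiative
#' "energy" integral per excitation window (`NR_266`, `NR_532`), the maximum
#' absolute deviation for radiative traces (`R_266`), and the pre-excitation
#' mean of the detection beam (the optical scattering baseline, `SCATTER`).
#'
#' @name signals
NULL

# sample index of the first sample at or after time t (0-based)
sample_at_or_after <- function(t_ns, time_step_ns) {
  as.integer(ceiling(t_ns / time_step_ns - 1e-9))
}

#' Split a raster's samples into per-excitation windows
#'
#' Partitions the sample axis into one half-open window per excitation event:
#' window i starts at the first sample at/after `event_time + guard` and ends
#' just before the first sample of the next event (or at `n_samples` for the
#' last event). With `guard = 0` the windows tile `[first event sample,
#' n_samples)` exactly.
#'
#' @param raster a [td_signal_raster].
#' @param guard_ns non-negative dead time (ns) skipped after each excitation
#'   edge before integration starts.
#' @return named list of [time_window]s, one per event label, in schedule
#'   order.
#' @export
split_excitation_windows <- function(raster, guard_ns = 0) {
  stopifnot(inherits(raster, "td_signal_raster"))
  if (guard_ns < 0) stop("`guard_ns` must be non-negative")
  sch <- raster$schedule
  if (nrow(sch) > 1L && any(diff(sch$time_ns) < guard_ns))
    stop("excitation events closer than the guard time: peaks are unseparable")
  dt <- raster$time_step_ns
  out <- vector("list", nrow(sch))
  for (i in seq_len(nrow(sch))) {
    start <- sample_at_or_after(sch$time_ns[i] + guard_ns, dt)
    end <- if (i < nrow(sch)) sample_at_or_after(sch$time_ns[i + 1], dt)
           else raster$n_samples
    if (start >= end)
      stop(sprintf("window for %s is empty (guard too large?)", sch$label[i]))
    out[[i]] <- time_window(start, end)
  }
  names(out) <- sch$label
  out
}

#' Pre-excitation window of a raster
#'
#' The samples strictly before the first excitation event; used for the
#' scattering baseline and for baseline subtraction of the modulation trace.
#'
#' @param raster a [td_signal_raster].
#' @return a [time_window], or `NULL` when no sample precedes the first event.
#' @export
pre_excitation_window <- function(raster) {
  first <- sample_at_or_after(raster$schedule$time_ns[1], raster$time_step_ns)
  if (first < 1L) return(NULL)
  time_window(0L, first)
}

# per-pixel signal matrix (pixels x samples); pixel order is column-major
# over the image, matching matrix(v, height, width)
signal_matrix <- function(raster) {
  matrix(raster$signals, raster$height * raster$width, raster$n_samples)
}

# per-pixel baseline: mean over the pre-excitation window, or 0 when the
# first event is at sample 0
pixel_baseline <- function(raster) {
  pw <- pre_excitation_window(raster)
  if (is.null(pw)) return(rep(0, raster$height * raster$width))
  idx <- window_indices(pw, raster$n_samples)
  m <- signal_matrix(raster)
  rowMeans(m[, idx, drop = FALSE])
}

#' Non-radiative integral channel
#'
#' Reduces each pixel's time-resolved trace to the post-excitation modulation
#' energy within a window: the sum of squared deviations from the pixel's
#' pre-excitation baseline, times the sample spacing. `energy = "abs"`
#' switches to the sum of absolute deviations (an L1 reading of the same
#' reduction).
#'
#' @param raster a [td_signal_raster].
#' @param window a [time_window] (typically from
#'   [split_excitation_windows()]).
#' @param energy `"squared"` (default) or `"abs"`.
#' @param name channel name for the result.
#' @return a [channel_image] of non-negative values.
#' @export
extract_nr_integral <- function(raster, window, energy = c("squared", "abs"),
                                name = "NR") {
  energy <- match.arg(energy)
  idx <- window_indices(window, raster$n_samples)
  m <- signal_matrix(raster)
  dev <- m[, idx, drop = FALSE] - pixel_baseline(raster)
  v <- if (energy == "squared") rowSums(dev^2) else rowSums(abs(dev))
  channel_image(matrix(v * raster$time_step_ns, raster$height, raster$width),
                name)
}

#' Amplitude channel
#'
#' Reduces each pixel's trace to the maximum absolute deviation from its
#' pre-excitation baseline within a window; the conventional reduction of
#' the radiative (optical emission) trace.
#'
#' @inheritParams extract_nr_integral
#' @return a [channel_image] of non-negative values.
#' @export
extract_amplitude <- function(raster, window, name = "R") {
  idx <- window_indices(window, raster$n_samples)
  m <- signal_matrix(raster)
  dev <- abs(m[, idx, drop = FALSE] - pixel_baseline(raster))
  v <- dev[, 1]
  for (j in seq_len(ncol(dev))[-1]) v <- pmax(v, dev[, j])
  channel_image(matrix(v, raster$height, raster$width), name)
}

#' Optical scattering baseline channel
#'
#' Per pixel, the mean of the transmitted detection intensity prior to any
#' excitation event.
#'
#' @param raster a [td_signal_raster].
#' @param pre_window a [time_window] that must end at or before the first
#'   excitation event's sample; defaults to the full pre-excitation span.
#' @return a [channel_image].
#' @export
extract_scatter_baseline <- function(raster, pre_window = NULL) {
  if (is.null(pre_window)) pre_window <- pre_excitation_window(raster)
  if (is.null(pre_window))
    stop("no samples precede the first excitation event")
  first <- sample_at_or_after(raster$schedule$time_ns[1], raster$time_step_ns)
  if (pre_window$end_index > first)
    stop("`pre_window` overlaps an excitation event")
  idx <- window_indices(pre_window, raster$n_samples)
  m <- signal_matrix(raster)
  v <- rowMeans(m[, idx, drop = FALSE])
  channel_image(matrix(v, raster$height, raster$width), "SCATTER")
}

#' Normalize, saturate and reverse a channel image
#'
#' The standard PARS display/preprocessing convention: clip at the
#' `saturation_fraction` and `1 - saturation_fraction` empirical quantiles
#' (linear-interpolation quantiles; 1% by default), rescale to `[0, 1]`, and
#' optionally reverse contrast (`1 - x`) so bright PARS absorption matches
#' the dark structures of grayscale H&E.
#'
#' @param img a [channel_image].
#' @param saturation_fraction fraction in `[0, 0.5)` saturated at each tail.
#' @param reverse reverse contrast after rescaling (default `TRUE`).
#' @return a [channel_image] with values in `[0, 1]`. A constant input has no
#'   contrast to normalize; it maps to all zeros (all ones when reversed)
#'   with a warning.
#' @export
preprocess_channel <- function(img, saturation_fraction = 0.01,
                               reverse = TRUE) {
  stopifnot(inherits(img, "channel_image"))
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    stop("`saturation_fraction` must lie in [0, 0.5)")
  v <- img$values
  q <- stats::quantile(v, c(saturation_fraction, 1 - saturation_fraction),
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant (zero-contrast) channel '", img$name, "'")
    out <- matrix(if (reverse) 1 else 0, img$height, img$width)
    return(channel_image(out, img$name))
  }
  out <- (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  if (reverse) out <- 1 - out
  channel_image(out, img$name)
}
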