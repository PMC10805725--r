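#' Time-resolved PARS signal raster
#'
#' Container for a field of view of per-pixel time-resolved non-radiative
#' (or radiative) PARS signals, together with the sampling time step and the
#' excitation-event schedule. Every per-pixel trace has `n_samples` samples
#' spaced `time_step` nanoseconds apart; excitation events (a 266 nm UV pulse
#' targeting DNA/RNA and, ~500 ns later, a 532 nm pulse targeting hemoglobin)
#' are recorded as `(label, time_ns)` rows ordered by time.
#'
#' @param signals numeric array of dimension `height x width x n_samples`;
#'   all values must be finite.
#' @param time_step_ns positive scalar, nanoseconds per sample.
#' @param schedule data frame with columns `label` (each one of `"EX266"`,
#'   `"EX532"`) and `time_ns`, strictly increasing and within
#'   `[0, n_samples * time_step_ns)`. When both wavelengths are present the
#'   532 nm event must follow the 266 nm event.
#'
#' @return an object of class `td_signal_raster` with fields `signals`,
#'   `height`, `width`, `n_samples`, `time_step_ns`, `schedule`.
#' @export
td_signal_raster <- function(signals, time_step_ns, schedule) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stop("`signals` must be a height x width x n_samples array")
  if (!all(is.finite(signals)))
    stop("`signals` must be finite everywhere")
  d <- dim(signals)
  if (d[3] < 2L) stop("need at least 2 samples per signal")
  if (!is.numeric(time_step_ns) || length(time_step_ns) != 1L || time_step_ns <= 0)
    stop("`time_step_ns` must be a positive scalar")
  schedule <- as.data.frame(schedule)
  if (!all(c("label", "time_ns") %in% names(schedule)))
    stop("`schedule` needs columns `label` and `time_ns`")
  if (nrow(schedule) < 1L) stop("`schedule` must contain at least one event")
  if (!all(schedule$label %in% c("EX266", "EX532")))
    stop("schedule labels must be EX266 or EX532")
  if (any(diff(schedule$time_ns) <= 0))
    stop("schedule times must be strictly increasing")
  t_max <- d[3] * time_step_ns
  if (any(schedule$time_ns < 0) || any(schedule$time_ns >= t_max))
    stop("schedule times must lie within [0, n_samples * time_step_ns)")
  if (all(c("EX266", "EX532") %in% schedule$label)) {
    t266 <- schedule$time_ns[match("EX266", schedule$label)]
    t532 <- schedule$time_ns[match("EX532", schedule$label)]
    if (t532 <= t266)
      stop("the 532 nm excitation must follow the 266 nm excitation")
  }
  structure(
    list(signals = signals, height = d[1], width = d[2], n_samples = d[3],
         time_step_ns = time_step_ns, schedule = schedule),
    class = "td_signal_raster")
}

#' @export
print.td_signal_raster <- function(x, ...) {
  cat(sprintf("<td_signal_raster> %d x %d pixels, %d samples @ %g ns\n",
              x$height, x$width, x$n_samples, x$time_step_ns))
  cat("  events:", paste(sprintf("%s@%gns", x$schedule$label, x$schedule$time_ns),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Half-open sample window
#'
#' A 0-based, half-open `[start_index, end_index)` range of sample indices
#' into a time-resolved signal. Integration and clustering windows are always
#' expressed this way; `end_index` may equal `n_samples`.
#'
#' @param start_index first sample (inclusive, 0-based).
#' @param end_index one past the last sample (exclusive).
#' @return a `time_window` object.
#' @export
time_window <- function(start_index, end_index) {
  start_index <- as.integer(start_index); end_index <- as.integer(end_index)
  if (start_index < 0L || start_index >= end_index)
    stop("need 0 <= start_index < end_index")
  structure(list(start_index = start_index, end_index = end_index),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window> [%d, %d)\n", x$start_index, x$end_index))
  invisible(x)
}

# 1-based R index vector for a window, validated against a raster
window_indices <- function(window, n_samples) {
  if (!inherits(window, "time_window")) stop("not a time_window")
  if (window$end_index > n_samples)
    stop("window extends past the end of the signal")
  (window$start_index + 1L):window$end_index
}

#' Single named grayscale channel image
#'
#' @param values numeric matrix (height x width), finite.
#' @param name channel label, e.g. `"NR_532"`, `"NR_266"`, `"R_266"`,
#'   `"SCATTER"` or `"m_f1"` ... `"m_fK"`.
#' @return a `channel_image` object.
#' @export
channel_image <- function(values, name) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (!is.character(name) || length(name) != 1L) stop("`name` must be a string")
  structure(list(values = values, name = name,
                 height = nrow(values), width = ncol(values)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s' %d x %d, range [%.4g, %.4g]\n",
              x$name, x$height, x$width, min(x$values), max(x$values)))
  invisible(x)
}

#' Ordered stack of co-dimensioned channel images
#'
#' The model's input domain A: an ordered, uniquely named list of grayscale
#' channels sharing one pixel grid (e.g. `NR_532, NR_266, R_266, m_f1, ...`).
#'
#' @param channels list of [channel_image] objects with unique names and
#'   identical dimensions.
#' @return a `channel_stack` object with fields `channels`, `height`, `width`.
#' @export
channel_stack <- function(channels) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty list")
  if (!all(vapply(channels, inherits, logical(1), "channel_image")))
    stop("all elements must be channel_image objects")
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms)) stop("channel names must be unique")
  hs <- vapply(channels, function(ch) ch$height, numeric(1))
  ws <- vapply(channels, function(ch) ch$width, numeric(1))
  if (length(unique(hs)) != 1L || length(unique(ws)) != 1L)
    stop("all channels must share dimensions")
  names(channels) <- nms
  structure(list(channels = channels, height = hs[1], width = ws[1]),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %d channel(s), %d x %d: %s\n",
              length(x$channels), x$height, x$width,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Channel names of a stack
#' @param stack a [channel_stack].
#' @return character vector of channel names in order.
#' @export
stack_names <- function(stack) names(stack$channels)

#' Convert a channel stack to a height x width x N array
#' @param stack a [channel_stack].
#' @return numeric array.
#' @export
stack_to_array <- function(stack) {
  arr <- array(0, c(stack$height, stack$width, length(stack$channels)))
  for (i in seq_along(stack$channels)) arr[, , i] <- stack$channels[[i]]$values
  dimnames(arr) <- list(NULL, NULL, names(stack$channels))
  arr
}

#' Select a subset of channels from a stack, preserving order
#' @param stack a [channel_stack].
#' @param names channel names to keep (must all exist).
#' @return a [channel_stack] with the requested channels, in the given order.
#' @export
stack_subset <- function(stack, names) {
  missing <- setdiff(names, stack_names(stack))
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  channel_stack(stack$channels[names])
}

#' Three-channel RGB image with values in [0, 1]
#'
#' @param values numeric array `height x width x 3`, values in `[0, 1]`.
#' @return an `rgb_image` object.
#' @export
rgb_image <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[3] != 3L)
    stop("`values` must be a height x width x 3 array")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (min(values) < 0 || max(values) > 1)
    stop("RGB values must lie in [0, 1]")
  structure(list(values = values, height = dim(values)[1],
                 width = dim(values)[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d\n", x$height, x$width))
  invisible(x)
}

#' A channel stack with its co-registered RGB ground truth
#'
#' The training unit of the colorization model: an input [channel_stack] and
#' the pixel-aligned true H&E [rgb_image] of the same field of view.
#'
#' @param stack a [channel_stack].
#' @param truth an [rgb_image] with matching dimensions.
#' @return a `registered_pair` object.
#' @export
registered_pair <- function(stack, truth) {
  if (!inherits(stack, "channel_stack")) stop("`stack` must be a channel_stack")
  if (!inherits(truth, "rgb_image")) stop("`truth` must be an rgb_image")
  if (stack$height != truth$height || stack$width != truth$width)
    stop("stack and truth must share dimensions")
  structure(list(stack = stack, truth = truth), class = "registered_pair")
}

#' @export
print.registered_pair <- function(x, ...) {
  cat(sprintf("<registered_pair> %d x %d, %d input channel(s)\n",
              x$stack$height, x$stack$width, length(x$stack$channels)))
  invisible(x)
}
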