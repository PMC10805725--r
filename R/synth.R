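#' Synthetic PARS tissue phantoms
#'
#' The phantom generator emulates the statistical structure that the
#' virtual-staining pipeline consumes, with no optical physics: per-pixel
#' non-radiative traces are noisy linear mixtures of a few characteristic
#' time-domain shapes tied to structure classes (nuclei, red blood cells,
#' connective tissue over a quiet background), the 266 nm-responsive shapes
#' peak in the first excitation window and the hemoglobin-like shape in the
#' 532 nm window ~500 ns later, a separate radiative raster responds at
#' 266 nm only, and a deterministic class-to-color map yields a co-registered
#' pseudo-H&E ground truth.
#'
#' @name synth
NULL

# damped-oscillation pulse template starting at t0, unit norm
td_shape_template <- function(n_samples, time_step_ns, t0_ns, tau_ns,
                              period_ns, phase = 0) {
  t <- (seq_len(n_samples) - 1L) * time_step_ns
  rel <- t - t0_ns
  s <- ifelse(rel >= 0,
              exp(-rel / tau_ns) * sin(2 * pi * rel / period_ns + phase), 0)
  sign_normalize(s / sqrt(sum(s^2)))
}

phantom_class <- function(name, shape, signal_scale, radiative_amplitude,
                          color, geometry = list()) {
  list(name = name, shape = shape, signal_scale = signal_scale,
       radiative_amplitude = radiative_amplitude, color = color,
       geometry = geometry)
}

#' Specification of a synthetic tissue phantom
#'
#' Defines the field-of-view geometry, the per-class time-domain basis
#' shapes, radiative amplitudes, H&E colors and structure geometry, the
#' additive noise level and the excitation schedule. The defaults follow the
#' acquisition conventions of two-wavelength PARS histology: 256 samples at
#' 4 ns (a ~1 us record), the 266 nm event at 100 ns (leaving a
#' pre-excitation baseline segment) and the 532 nm event 500 ns later.
#'
#' @param height,width phantom dimensions in pixels.
#' @param tissue `"skin"` (nuclei + red blood cells + connective; three
#'   active signal classes) or `"brain"` (nuclei + connective; two).
#' @param noise_sd additive Gaussian noise per sample (default 0.01; class
#'   weights are O(1) and the unit-norm basis shapes peak near 0.2, so this
#'   puts the peak-amplitude SNR around 20, typical of averaged PARS
#'   acquisitions).
#' @param baseline_level constant detection-beam level added to every trace
#'   (default 1).
#' @param n_samples,time_step_ns sampling of the time axis.
#' @param seed integer seed controlling all phantom randomness.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         tissue = c("skin", "brain"),
                         noise_sd = 0.01, baseline_level = 1,
                         n_samples = 256L, time_step_ns = 4,
                         seed = 1L) {
  tissue <- match.arg(tissue)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  t266 <- 100; t532 <- 600
  shp <- function(t0, tau, period, phase = 0)
    td_shape_template(n_samples, time_step_ns, t0, tau, period, phase)
  classes <- list(
    phantom_class("nucleus",
                  shp(t266, 120, 150), signal_scale = 1.0,
                  radiative_amplitude = 0.25,
                  color = c(0.36, 0.21, 0.56),
                  geometry = list(kind = "disk", density = 1.2e-3,
                                  radius = c(6, 12))),
    phantom_class("connective",
                  shp(t266, 320, 300, phase = pi / 3), signal_scale = 0.7,
                  radiative_amplitude = 1.0,
                  color = c(0.91, 0.58, 0.69),
                  geometry = list(kind = "texture", coverage = 0.5,
                                  corr_sigma = 8)))
  if (tissue == "skin")
    classes <- append(classes, list(
      phantom_class("rbc",
                    shp(t532, 150, 180), signal_scale = 1.2,
                    radiative_amplitude = 0.05,
                    color = c(0.77, 0.15, 0.19),
                    geometry = list(kind = "disk", density = 8e-4,
                                    radius = c(3.5, 6)))), 1)
  classes <- append(classes, list(
    phantom_class("background", rep(0, n_samples), signal_scale = 0,
                  radiative_amplitude = 0.01,
                  color = c(0.97, 0.96, 0.97),
                  geometry = list(kind = "rest"))))
  active <- Filter(function(cl) cl$signal_scale > 0, classes)
  for (i in seq_along(active)[-1]) for (j in seq_len(i - 1)) {
    d <- angular_distance(active[[i]]$shape, active[[j]]$shape)
    if (d <= 0.1)
      stop(sprintf("class shapes '%s' and '%s' are near-collinear (%.3f)",
                   active[[i]]$name, active[[j]]$name, d))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 tissue = tissue, classes = classes, noise_sd = noise_sd,
                 baseline_level = baseline_level,
                 n_samples = as.integer(n_samples),
                 time_step_ns = time_step_ns,
                 schedule = data.frame(label = c("EX266", "EX532"),
                                       time_ns = c(t266, t532)),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, %d x %d, %d classes, noise_sd = %g, seed = %d\n",
              x$tissue, x$height, x$width, length(x$classes), x$noise_sd,
              x$seed))
  invisible(x)
}

#' Number of active (signal-carrying) classes of a phantom spec
#' @param spec a [phantom_spec].
#' @return integer: the true number of distinct time-domain shapes present.
#' @export
phantom_k_true <- function(spec) {
  sum(vapply(spec$classes, function(cl) cl$signal_scale > 0, logical(1)))
}

# paint filled disks with random centers/radii onto a label matrix
paint_disks <- function(label, value, n, radius_range) {
  h <- nrow(label); w <- ncol(label)
  if (n < 1L) return(label)
  cx <- stats::runif(n, 1, w); cy <- stats::runif(n, 1, h)
  rr <- stats::runif(n, radius_range[1], radius_range[2])
  for (i in seq_len(n)) {
    x0 <- max(1L, floor(cx[i] - rr[i])); x1 <- min(w, ceiling(cx[i] + rr[i]))
    y0 <- max(1L, floor(cy[i] - rr[i])); y1 <- min(h, ceiling(cy[i] + rr[i]))
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    sub <- label[ys, xs, drop = FALSE]
    sub[d2 <= rr[i]^2] <- value
    label[ys, xs] <- sub
  }
  label
}

#' Generate a synthetic phantom field of view
#'
#' Seeded placement of nuclear disks, red-blood-cell blobs and connective
#' texture over background; per-pixel non-radiative trace = baseline +
#' sum over classes of weight x shape + Gaussian noise; a radiative raster
#' responding in the 266 nm window only; and the pseudo-H&E color blend of
#' the class weights (the registered ground truth). All outputs share one
#' pixel grid.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `nr_raster` and `r_raster`
#'   ([td_signal_raster]s), `truth` (list: `label` matrix of class names,
#'   `weights` `H x W x n_classes` array, `basis` matrix of active-class
#'   shapes in columns, `class_names`), and `he` (the ground-truth
#'   [rgb_image]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; n <- spec$n_samples
  cls <- spec$classes
  nm <- vapply(cls, function(cl) cl$name, character(1))
  with_seed(spec$seed, {
    # label map: background, then texture, then painted structures on top
    label <- matrix("background", h, w)
    for (ci in seq_along(cls)) {
      g <- cls[[ci]]$geometry
      if (identical(g$kind, "texture")) {
        field <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), g$corr_sigma)
        label[field > stats::quantile(field, 1 - g$coverage)] <- nm[ci]
      }
    }
    for (ci in seq_along(cls)) {
      g <- cls[[ci]]$geometry
      if (identical(g$kind, "disk"))
        label <- paint_disks(label, nm[ci],
                             n = max(1L, round(g$density * h * w)),
                             radius_range = g$radius)
    }
    # smooth one-hot weights with mild per-pixel amplitude jitter
    weights <- array(0, c(h, w, length(cls)))
    jitter <- pmax(0.25, 1 + 0.25 * gaussian_blur(matrix(stats::rnorm(h * w), h, w), 2))
    for (ci in seq_along(cls))
      weights[, , ci] <- gaussian_blur((label == nm[ci]) * 1, 0.6) * jitter
    dimnames(weights) <- list(NULL, NULL, nm)

    active <- which(vapply(cls, function(cl) cl$signal_scale > 0, logical(1)))
    basis <- vapply(cls[active], function(cl) cl$shape, numeric(n))
    colnames(basis) <- nm[active]

    # non-radiative raster: baseline + weighted shapes + noise
    wmat <- matrix(weights, h * w, length(cls))[, active, drop = FALSE]
    scales <- vapply(cls[active], function(cl) cl$signal_scale, numeric(1))
    sig <- spec$baseline_level + (wmat %*% (t(basis) * scales))
    if (spec$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(length(sig), sd = spec$noise_sd),
                          nrow(sig), ncol(sig))
    nr_raster <- td_signal_raster(array(sig, c(h, w, n)),
                                  spec$time_step_ns, spec$schedule)

    # radiative raster: one emission pulse shape in the 266 nm window only.
    # Autofluorescence yields are broadly overlapping across tissue
    # components, so each class's amplitude is modulated by a smooth
    # within-class variability field: the radiative channel correlates
    # with, but does not determine, the structure class -- the premise
    # under which time-domain features add labeling information
    r_shape <- td_shape_template(n, spec$time_step_ns,
                                 spec$schedule$time_ns[1], 80, 320,
                                 phase = pi / 2)
    r_amp <- matrix(0, h, w)
    for (ci in seq_along(cls)) {
      field <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), 10)
      field <- field / max(stats::sd(field), 1e-12)
      r_jit <- pmax(0.15, 1 + 0.6 * field)
      r_amp <- r_amp + weights[, , ci] * cls[[ci]]$radiative_amplitude * r_jit
    }
    r_sig <- spec$baseline_level + outer(as.vector(r_amp), r_shape)
    if (spec$noise_sd > 0)
      r_sig <- r_sig + matrix(stats::rnorm(length(r_sig), sd = spec$noise_sd),
                              nrow(r_sig), ncol(r_sig))
    r_raster <- td_signal_raster(array(r_sig, c(h, w, n)),
                                 spec$time_step_ns, spec$schedule)

    # pseudo-H&E: blend class colors by (normalized) weights
    wsum <- pmax(1, apply(weights, c(1, 2), sum))
    he <- array(0, c(h, w, 3))
    for (ci in seq_along(cls)) for (ch in 1:3)
      he[, , ch] <- he[, , ch] + weights[, , ci] / wsum * cls[[ci]]$color[ch]
    rest <- pmax(0, 1 - apply(weights, c(1, 2), sum) / wsum)
    bg_col <- cls[[which(nm == "background")]]$color
    for (ch in 1:3) he[, , ch] <- pmin(1, pmax(0, he[, , ch] + rest * bg_col[ch]))

    list(nr_raster = nr_raster, r_raster = r_raster,
         truth = list(label = label, weights = weights, basis = basis,
                      class_names = nm),
         he = rgb_image(he))
  })
}

#' Extract the conventional channel stack of a phantom (or real) acquisition
#'
#' Builds the preprocessed `NR_532`, `NR_266` and `R_266` channels and, when
#' a [feature_set] is supplied, the preprocessed feature images
#' `m_f1 ... m_fK`, all co-registered on the raster's pixel grid.
#'
#' @param nr_raster non-radiative [td_signal_raster].
#' @param r_raster radiative [td_signal_raster] (amplitude is taken in the
#'   266 nm window).
#' @param fs optional [feature_set] for appending unmixed feature channels.
#' @param guard_ns guard time for window splitting.
#' @param energy energy definition for the NR integral.
#' @return a [channel_stack] ordered `NR_532, NR_266, R_266, m_f1, ...`.
#' @export
build_channel_stack <- function(nr_raster, r_raster, fs = NULL, guard_ns = 0,
                                energy = "squared") {
  win <- split_excitation_windows(nr_raster, guard_ns)
  chans <- list(
    preprocess_channel(extract_nr_integral(nr_raster, win$EX532,
                                           energy = energy, name = "NR_532")),
    preprocess_channel(extract_nr_integral(nr_raster, win$EX266,
                                           energy = energy, name = "NR_266")),
    preprocess_channel(extract_amplitude(r_raster,
                                         split_excitation_windows(r_raster)$EX266,
                                         name = "R_266")))
  if (!is.null(fs)) {
    fi <- unmix(nr_raster, fs)
    chans <- c(chans, lapply(fi$images, preprocess_channel))
  }
  channel_stack(chans)
}

#' Build a partitioned patch dataset from phantom fields of view
#'
#' Generates `n_fovs` phantoms (seeded `spec$seed + fov - 1`), learns a
#' feature basis of size `K` on the first field of view when requested,
#' extracts overlapping `patch_size` patches with a stride chosen to
#' approximate `target_patches` in total, and assigns whole fields of view
#' (never individual patches) to the train/validation/test splits --
#' region-level disjointness prevents overlap leakage between splits. Counts
#' per split are floors of the ratios with the remainder assigned to train.
#'
#' @param spec a [phantom_spec] (per-FOV seeds derive from `spec$seed`).
#' @param n_fovs number of fields of view.
#' @param patch_size square patch side in pixels.
#' @param target_patches approximate total patch count across all FOVs.
#' @param split train/validation/test fractions summing to 1 (default
#'   `c(0.7, 0.1, 0.2)`).
#' @param K optional cluster count; when given, features are learned on FOV 1
#'   and unmixed into every stack.
#' @return list with `train`, `val`, `test` (lists of [registered_pair]
#'   patches), `fov_split` (per-FOV assignment) and `feature_set`.
#' @export
make_dataset <- function(spec, n_fovs = 5L, patch_size = 64L,
                         target_patches = 100L,
                         split = c(0.7, 0.1, 0.2), K = NULL) {
  if (abs(sum(split) - 1) > 1e-8) stop("`split` must sum to 1")
  if (patch_size > spec$height || patch_size > spec$width)
    stop("patch larger than the field of view")
  n_train <- floor(split[1] * n_fovs)
  n_val <- floor(split[2] * n_fovs)
  n_test <- floor(split[3] * n_fovs)
  n_train <- n_train + (n_fovs - n_train - n_val - n_test)
  assignment <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))

  per_fov <- max(1, round(target_patches / n_fovs))
  stride <- choose_stride(spec$height, spec$width, patch_size, per_fov)

  fs <- NULL
  out <- list(train = list(), val = list(), test = list())
  for (fov in seq_len(n_fovs)) {
    sp <- spec
    sp$seed <- spec$seed + fov - 1L
    ph <- generate_phantom(sp)
    if (!is.null(K) && is.null(fs))
      fs <- learn_features(ph$nr_raster, K = K, seed = spec$seed)
    stack <- build_channel_stack(ph$nr_raster, ph$r_raster, fs = fs)
    grid <- patch_grid(spec$height, spec$width, patch_size, stride)
    arr <- stack_to_array(stack)
    for (g in seq_len(nrow(grid$coords))) {
      ys <- grid$coords$row[g] + seq_len(patch_size) - 1L
      xs <- grid$coords$col[g] + seq_len(patch_size) - 1L
      p_stack <- channel_stack(lapply(seq_len(dim(arr)[3]), function(ci)
        channel_image(arr[ys, xs, ci], stack_names(stack)[ci])))
      p_truth <- rgb_image(ph$he$values[ys, xs, , drop = FALSE])
      out[[assignment[fov]]] <-
        c(out[[assignment[fov]]], list(registered_pair(p_stack, p_truth)))
    }
  }
  list(train = out$train, val = out$val, test = out$test,
       fov_split = assignment, feature_set = fs,
       stride = stride, patch_size = patch_size)
}

# stride giving a per-FOV patch count closest to `target` (larger stride on
# ties); counts come from the clamped patch grid
choose_stride <- function(height, width, patch_size, target) {
  best_s <- patch_size; best_err <- Inf
  for (s in seq_len(patch_size)) {
    n <- patch_grid_count(height, patch_size, s) *
      patch_grid_count(width, patch_size, s)
    err <- abs(n - target)
    if (err < best_err || (err == best_err && s > best_s)) {
      best_err <- err; best_s <- s
    }
  }
  best_s
}
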