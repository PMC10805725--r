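#' Angular (sine-of-angle) distance between two signal shapes
#'
#' Time-resolved signals are treated as rays through the origin of R^n: two
#' signals that differ only by a (possibly negative) scale factor have the
#' same shape. The distance between two shapes is the sine of the acute angle
#' between their rays: 0 for scaled or inverted copies, 1 for orthogonal
#' signals.
#'
#' @param x,y numeric vectors of equal length, not both zero.
#' @return `sin(theta)` in `[0, 1]`.
#' @export
angular_distance <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  nx2 <- sum(x^2); ny2 <- sum(y^2)
  if (nx2 == 0 || ny2 == 0)
    stop("angular distance is undefined for a zero vector")
  c2 <- sum(x * y)^2 / (nx2 * ny2)
  sqrt(max(0, 1 - min(1, c2)))
}

# orient a vector so its largest-magnitude element is positive
sign_normalize <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Sign-invariant principal-component centroid
#'
#' The centroid of a cluster of signal shapes is the principal component of
#' the cluster unioned with its negation: the direction maximizing the summed
#' squared projections of the members, i.e. the leading right singular vector
#' of the member matrix. It is invariant to negating any member and robust to
#' noise (unlike the arithmetic mean of sign-ambiguous signals, which can
#' cancel).
#'
#' @param member_signals numeric matrix, one member signal per row; at least
#'   one non-zero row.
#' @return unit-norm numeric vector, oriented so its largest-magnitude
#'   element is positive.
#' @export
update_centroid <- function(member_signals) {
  if (is.vector(member_signals))
    member_signals <- matrix(member_signals, nrow = 1)
  if (nrow(member_signals) < 1L || all(member_signals == 0))
    stop("centroid update needs at least one non-zero member")
  v <- svd(member_signals)$v[, 1]
  sign_normalize(v / sqrt(sum(v^2)))
}

#' Learned time-domain feature set
#'
#' The output of K*-means: `K` unit-norm centroid shapes `f_1 ... f_K` of
#' length `n_samples`, arranged column-wise in the feature matrix `F` used
#' for pseudo-inverse unmixing, plus fit metadata.
#'
#' @param feature_matrix numeric `n_samples x K` matrix whose columns are the
#'   unit-norm centroids.
#' @param meta list of fit metadata (seed, iterations, converged, inertia,
#'   subset size).
#' @param k_max upper bound on `K` (default 6, guarding against redundant
#'   clusters).
#' @return a `feature_set` object with fields `K`, `n_samples`,
#'   `feature_matrix` (centroid `i` is column `i`) and `meta`.
#' @export
feature_set <- function(feature_matrix, meta = list(), k_max = 6L) {
  if (!is.matrix(feature_matrix)) stop("`feature_matrix` must be a matrix")
  K <- ncol(feature_matrix)
  if (K < 2L || K > k_max)
    stop(sprintf("K must lie in [2, %d]", k_max))
  norms <- sqrt(colSums(feature_matrix^2))
  if (any(abs(norms - 1) > 1e-8)) stop("centroids must have unit norm")
  for (k in seq_len(K)) {
    v <- feature_matrix[, k]
    if (v[which.max(abs(v))] < 0)
      stop("centroids must be oriented with largest-magnitude element positive")
  }
  structure(list(K = K, n_samples = nrow(feature_matrix),
                 feature_matrix = feature_matrix, meta = meta),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> K = %d, n_samples = %d, converged = %s\n",
              x$K, x$n_samples,
              if (isTRUE(x$meta$converged)) "yes" else "no"))
  invisible(x)
}

# squared-cosine similarity of rows of sn (unit rows) against centroids
# (columns of cf, unit columns); returns m x K matrix
cos2_matrix <- function(sn, cf) (sn %*% cf)^2

# k-means++ seeding under the angular distance: each subsequent seed is
# sampled with probability proportional to its squared distance from the
# picked set. Mass-weighted sampling (rather than a farthest-point argmax)
# keeps rare noise-dominated outlier pixels from capturing seeds.
kstar_init <- function(sn, K, seed) {
  m <- nrow(sn)
  with_seed(seed, {
    picked <- integer(K)
    picked[1] <- sample.int(m, 1L)
    best_d2 <- 1 - (sn %*% sn[picked[1], ])^2
    if (K > 1L) for (k in 2L:K) {
      p <- pmax(best_d2, 0)
      picked[k] <- if (sum(p) <= 0) sample.int(m, 1L)
                   else sample.int(m, 1L, prob = p)
      best_d2 <- pmin(best_d2, 1 - (sn %*% sn[picked[k], ])^2)
    }
    picked
  })
}

#' K*-means clustering of signal shapes
#'
#' K-means under the sine-of-angle distance, with centroids computed as the
#' sign-invariant principal component of each cluster (see
#' [update_centroid()]). Initialization is seeded k-means++ sampling under
#' the angular distance; iteration alternates assignment and centroid
#' update until the largest centroid movement (old vs. new angular
#' distance) drops below `tol` or `max_iter` is reached. Centroid updates
#' use direction-normalized members, so every sweep exactly minimizes the
#' inertia (the sum of squared assigned distances), which is therefore
#' non-increasing across iterations. Because a single Lloyd descent can
#' stall in a poor local optimum, `n_init` restarts are run and the
#' lowest-inertia solution kept; a final trimmed refinement re-estimates
#' each centroid from its best-fitting members.
#'
#' @param signals numeric matrix, one signal per row; rows must be non-zero
#'   (pre-filter dead pixels with [filter_dead_pixels()]).
#' @param K number of clusters, in `[2, k_max]` and at most `nrow(signals)`.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 100).
#' @param tol angular-distance convergence tolerance on centroid movement
#'   (default 1e-4).
#' @param k_max upper bound on `K` (default 6).
#' @param n_init number of restarts (default 5); the lowest-inertia run
#'   wins.
#' @param trim fraction of each cluster's worst-fitting members excluded
#'   during a final trimmed centroid refinement (default 0.2; 0 disables).
#'   Boundary pixels mixing two structures fall in this tail and would
#'   otherwise bias the learned shapes.
#' @return list with elements `feature_set` (a [feature_set]) and
#'   `assignment` (list with per-signal `cluster` in `1..K`, `distance` in
#'   `[0, 1]`, and the per-iteration `inertia` trace).
#' @export
kstar_cluster <- function(signals, K, seed = 1L, max_iter = 100L,
                          tol = 1e-4, k_max = 6L, n_init = 5L, trim = 0.2) {
  if (!is.matrix(signals)) stop("`signals` must be a matrix")
  K <- as.integer(K)
  if (K < 2L || K > k_max) stop(sprintf("K must lie in [2, %d]", k_max))
  m <- nrow(signals)
  if (m < K) stop("fewer signals than clusters")
  best <- NULL
  for (restart in seq_len(n_init)) {
    run <- kstar_once(signals, K, seed + 101L * (restart - 1L), max_iter,
                      tol, k_max, trim)
    if (is.null(best) ||
        run$feature_set$meta$inertia < best$feature_set$meta$inertia)
      best <- run
  }
  best$feature_set$meta$seed <- seed
  best$feature_set$meta$n_init <- n_init
  best
}

kstar_once <- function(signals, K, seed, max_iter, tol, k_max, trim = 0.2) {
  m <- nrow(signals)
  norms <- sqrt(rowSums(signals^2))
  if (any(norms == 0)) stop("zero-norm signals present; filter dead pixels first")
  sn <- signals / norms

  centroids <- t(sn[kstar_init(sn, K, seed), , drop = FALSE])
  centroids <- apply(centroids, 2, sign_normalize)
  inertia_trace <- numeric(0)
  cluster <- integer(m)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    c2 <- cos2_matrix(sn, centroids)
    cluster <- max.col(c2, ties.method = "first")
    d2 <- pmax(0, 1 - c2[cbind(seq_len(m), cluster)])
    inertia_trace <- c(inertia_trace, sum(d2))
    # re-seed empty clusters from the worst-fit signal
    for (k in which(tabulate(cluster, K) == 0L)) {
      far <- which.max(d2)
      message("re-seeding empty cluster ", k, " from signal ", far)
      cluster[far] <- k
      d2[far] <- 0
    }
    # centroids from direction-normalized members: the principal component
    # of the unit signals (with their negations) is the exact minimizer of
    # the cluster's summed squared angular distance, making each sweep a
    # monotone descent; raw-amplitude members would overweight bright pixels
    new_centroids <- centroids
    for (k in seq_len(K)) {
      members <- sn[cluster == k, , drop = FALSE]
      new_centroids[, k] <- update_centroid(members)
    }
    movement <- max(vapply(seq_len(K), function(k)
      angular_distance(centroids[, k], new_centroids[, k]), numeric(1)))
    centroids <- new_centroids
    if (movement < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # trimmed refinement: pixels straddling structure boundaries carry
  # mixtures of two shapes and sit in their cluster's worst-fit tail;
  # re-estimating each centroid from its best-fitting members strips that
  # bias from the learned shapes
  if (trim > 0) for (pass in 1:2) {
    c2 <- cos2_matrix(sn, centroids)
    cluster <- max.col(c2, ties.method = "first")
    d2 <- pmax(0, 1 - c2[cbind(seq_len(m), cluster)])
    for (k in seq_len(K)) {
      dk <- d2[cluster == k]
      if (length(dk) < 2L) next
      keep <- dk <= stats::quantile(dk, 1 - trim, names = FALSE)
      if (any(keep))
        centroids[, k] <- update_centroid(
          sn[cluster == k, , drop = FALSE][keep, , drop = FALSE])
    }
  }
  c2 <- cos2_matrix(sn, centroids)
  cluster <- max.col(c2, ties.method = "first")
  d <- sqrt(pmax(0, 1 - c2[cbind(seq_len(m), cluster)]))
  fs <- feature_set(centroids,
                    meta = list(seed = seed, iterations = iter,
                                converged = converged,
                                inertia = sum(d^2),
                                subset_size = m),
                    k_max = k_max)
  list(feature_set = fs,
       assignment = list(cluster = cluster, distance = d,
                         inertia = inertia_trace))
}

#' Identify usable (non-dead) pixel signals
#'
#' Pixels without absorbing material carry no shape information -- their
#' windowed trace is detection noise. A row is dead when its Euclidean norm
#' falls below a relative floor (`threshold_factor` times the median norm)
#' or, when the acquisition noise level is known, when its squared norm is
#' consistent with pure noise: a noise-only squared norm follows
#' `noise_sd^2 * chi^2_n`, so rows below the upper `1 - alpha` quantile of
#' that distribution are rejected. Dead pixels are excluded from feature
#' learning and assigned zero amplitudes during unmixing.
#'
#' @param signals numeric matrix, one baseline-subtracted signal per row.
#' @param threshold_factor relative norm threshold (default 1e-3).
#' @param noise_sd optional per-sample noise standard deviation (e.g. from
#'   [estimate_noise_sd()]).
#' @param alpha tail probability of falsely keeping a noise-only pixel
#'   (default 1e-4).
#' @return logical vector, `TRUE` for usable rows.
#' @export
filter_dead_pixels <- function(signals, threshold_factor = 1e-3,
                               noise_sd = NULL, alpha = 1e-4) {
  norms2 <- rowSums(signals^2)
  thr2 <- (threshold_factor^2) * stats::median(norms2)
  if (!is.null(noise_sd) && noise_sd > 0)
    thr2 <- max(thr2, noise_sd^2 *
                  stats::qchisq(1 - alpha, df = ncol(signals)))
  norms2 > thr2
}

#' Estimate the per-sample acquisition noise level of a raster
#'
#' Pooled standard deviation of the pre-excitation samples about their
#' per-pixel mean: before any excitation event the detection beam carries
#' only its baseline plus noise, so these residuals measure the noise floor
#' directly.
#'
#' @param raster a [td_signal_raster].
#' @return scalar noise standard deviation; 0 when no pre-excitation sample
#'   exists (noise then unknown).
#' @export
estimate_noise_sd <- function(raster) {
  pw <- pre_excitation_window(raster)
  if (is.null(pw) || pw$end_index < 2L) return(0)
  idx <- window_indices(pw, raster$n_samples)
  m <- signal_matrix(raster)[, idx, drop = FALSE]
  res <- m - rowMeans(m)
  sqrt(sum(res^2) / (nrow(m) * (ncol(m) - 1L)))
}

# baseline-subtracted, windowed per-pixel signal matrix
windowed_signals <- function(raster, window) {
  idx <- window_indices(window, raster$n_samples)
  signal_matrix(raster)[, idx, drop = FALSE] - pixel_baseline(raster)
}

#' Learn time-domain features from a raster
#'
#' Samples a seeded uniform random subset of pixels, restricts their
#' baseline-subtracted traces to `window`, drops dead pixels, and runs
#' [kstar_cluster()].
#'
#' @param raster a [td_signal_raster].
#' @param window a [time_window]; defaults to the full span from the first
#'   excitation event onward (both excitation peaks).
#' @param K number of features to learn.
#' @param subset_fraction fraction of pixels used for learning, in `(0, 1]`
#'   (default 0.1).
#' @param seed integer seed (subsampling and initialization).
#' @param ... passed on to [kstar_cluster()].
#' @return a [feature_set].
#' @export
learn_features <- function(raster, window = NULL, K, subset_fraction = 0.1,
                           seed = 1L, ...) {
  if (subset_fraction <= 0 || subset_fraction > 1)
    stop("`subset_fraction` must lie in (0, 1]")
  if (is.null(window)) {
    first <- sample_at_or_after(raster$schedule$time_ns[1], raster$time_step_ns)
    window <- time_window(first, raster$n_samples)
  }
  s <- windowed_signals(raster, window)
  noise_sd <- estimate_noise_sd(raster)
  m <- nrow(s)
  n_sub <- max(1L, floor(subset_fraction * m))
  take <- if (n_sub < m) with_seed(seed, sample.int(m, n_sub)) else seq_len(m)
  s <- s[take, , drop = FALSE]
  s <- s[filter_dead_pixels(s, noise_sd = noise_sd), , drop = FALSE]
  if (nrow(s) < K)
    stop("too few usable signals in the learning subset")
  res <- kstar_cluster(s, K, seed = seed, ...)
  res$feature_set$meta$subset_fraction <- subset_fraction
  res$feature_set$meta$subset_size <- nrow(s)
  res$feature_set$meta$window <- c(window$start_index, window$end_index)
  res$feature_set
}

#' Unmix a raster against a learned feature set
#'
#' Projects every pixel's baseline-subtracted, windowed trace `s` onto the
#' feature basis by the Moore-Penrose pseudo-inverse: amplitudes
#' `a = F^+ s`, the least-squares solution of `F a ~ s`. Dead pixels receive
#' zero amplitudes.
#'
#' @param raster a [td_signal_raster].
#' @param fs a [feature_set]; `ncol(F)` must be full rank and `nrow(F)` must
#'   equal the window length.
#' @param window a [time_window] matching the one used for learning;
#'   defaults to the window recorded in `fs$meta`.
#' @param rtol relative singular-value cutoff for the pseudo-inverse
#'   (default 1e-10).
#' @return a `feature_images` object: list with `images` (K [channel_image]s
#'   named `m_f1 ... m_fK`) and `feature_set` (provenance).
#' @export
unmix <- function(raster, fs, window = NULL, rtol = 1e-10) {
  stopifnot(inherits(fs, "feature_set"))
  if (is.null(window)) {
    if (is.null(fs$meta$window))
      stop("no window given and none recorded in the feature set")
    window <- time_window(fs$meta$window[1], fs$meta$window[2])
  }
  fmat <- fs$feature_matrix
  if (window$end_index - window$start_index != nrow(fmat))
    stop("window length must equal the centroid length")
  sv <- svd(fmat)$d
  if (sv[length(sv)] <= rtol * sv[1]) {
    dmin <- Inf; pair <- c(NA, NA)
    for (i in seq_len(fs$K - 1)) for (j in (i + 1):fs$K) {
      dij <- angular_distance(fmat[, i], fmat[, j])
      if (dij < dmin) { dmin <- dij; pair <- c(i, j) }
    }
    stop(sprintf(
      "feature matrix is rank deficient: centroids %d and %d are near-collinear (angular distance %.2e)",
      pair[1], pair[2], dmin))
  }
  s <- windowed_signals(raster, window)
  amps <- s %*% t(pinv_svd(fmat, rtol))
  amps[!filter_dead_pixels(s, noise_sd = estimate_noise_sd(raster)), ] <- 0
  images <- lapply(seq_len(fs$K), function(k)
    channel_image(matrix(amps[, k], raster$height, raster$width),
                  paste0("m_f", k)))
  names(images) <- vapply(images, function(im) im$name, character(1))
  structure(list(images = images, feature_set = fs),
            class = "feature_images")
}

#' @export
print.feature_images <- function(x, ...) {
  cat(sprintf("<feature_images> %d feature image(s): %s\n",
              length(x$images), paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Match two feature bases by angular distance
#'
#' Finds the permutation of the columns of `basis` minimizing the summed
#' angular distance to the columns of `reference` (brute force; intended for
#' `K <= 6`). Useful for comparing learned centroids against a known
#' generating basis or across seeds.
#'
#' @param basis,reference numeric matrices with the same number of columns
#'   (shapes in columns).
#' @return list with `perm` (column `k` of `reference` matches column
#'   `perm[k]` of `basis`), `distances` (per-match angular distance) and
#'   `total` (their sum).
#' @export
match_features <- function(basis, reference) {
  K <- ncol(reference)
  if (ncol(basis) != K) stop("bases must have the same number of columns")
  d <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    d[i, j] <- angular_distance(reference[, i], basis[, j])
  perms <- permutations(K)
  costs <- apply(perms, 1, function(p) sum(d[cbind(seq_len(K), p)]))
  best <- perms[which.min(costs), ]
  list(perm = best, distances = d[cbind(seq_len(K), best)],
       total = min(costs))
}
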