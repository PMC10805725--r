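#' Model-selection studies
#'
#' Two selection protocols choose the model inputs. The K-study picks the
#' number of time-domain features: for each K in range, features are learned
#' and unmixed, a colorization model is trained on the radiative channel
#' plus the K feature images (the radiative contrast is independent of the
#' non-radiative features, so it is always included for a fair comparison),
#' and held-out SSIM decides the winner. The C-study then searches all
#' `2^N - 1` subsets of the full channel array
#' `A = [NR_532, NR_266, R_266, m_f1 ... m_fK]` exhaustively, ranking each
#' trained subset per metric.
#'
#' Both studies split a field of view into disjoint vertical bands
#' (train/validation/test); patches never cross band boundaries, so
#' overlapping-patch leakage between partitions is impossible.
#'
#' @name studies
NULL

# crop a raster to a pixel region (rows/cols are 1-based index vectors)
crop_raster <- function(raster, rows, cols) {
  td_signal_raster(raster$signals[rows, cols, , drop = FALSE],
                   raster$time_step_ns, raster$schedule)
}

crop_stack <- function(stack, rows, cols) {
  channel_stack(lapply(stack$channels, function(ch)
    channel_image(ch$values[rows, cols, drop = FALSE], ch$name)))
}

crop_rgb <- function(img, rows, cols) {
  rgb_image(img$values[rows, cols, , drop = FALSE])
}

# vertical train/val/test bands of a field of view; every band with a
# positive fraction must fit at least one patch column
band_layout <- function(height, width, patch_size, split = c(0.7, 0.1, 0.2)) {
  if (abs(sum(split) - 1) > 1e-8) stop("`split` must sum to 1")
  edges <- round(cumsum(c(0, split)) * width)
  bands <- list()
  nms <- c("train", "val", "test")
  for (i in 1:3) {
    if (split[i] <= 0) next
    cols <- (edges[i] + 1L):edges[i + 1L]
    if (length(cols) < patch_size)
      stop(sprintf("band '%s' is narrower than the patch size", nms[i]))
    bands[[nms[i]]] <- cols
  }
  bands
}

# registered patch pairs from one region of a stack + truth
pairs_from_region <- function(stack, truth, rows, cols, patch_size, stride) {
  sub_stack <- crop_stack(stack, rows, cols)
  sub_truth <- crop_rgb(truth, rows, cols)
  grid <- patch_grid(length(rows), length(cols), patch_size, stride)
  arr <- stack_to_array(sub_stack)
  nms <- stack_names(sub_stack)
  lapply(seq_len(nrow(grid$coords)), function(g) {
    ys <- grid$coords$row[g] + seq_len(patch_size) - 1L
    xs <- grid$coords$col[g] + seq_len(patch_size) - 1L
    registered_pair(
      channel_stack(lapply(seq_along(nms), function(ci)
        channel_image(arr[ys, xs, ci], nms[ci]))),
      rgb_image(sub_truth$values[ys, xs, , drop = FALSE]))
  })
}

# duplicate the last channel of a stack until it has n channels (the same
# expansion rule the target side uses, applied to sub-3-channel subsets)
expand_stack_channels <- function(stack, n) {
  chans <- stack$channels
  last <- chans[[length(chans)]]
  k <- 1L
  while (length(chans) < n) {
    chans[[length(chans) + 1L]] <-
      channel_image(last$values, paste0(last$name, "_dup", k))
    k <- k + 1L
  }
  channel_stack(chans)
}

# train on the train band and score on the test band; shared by both studies
train_and_score <- function(stack, truth, cfg, split, train_stride,
                            metric_sigma, overlap = 0.5) {
  bands <- band_layout(stack$height, stack$width, cfg$patch_size, split)
  n_model <- max(3L, length(stack$channels))
  stack_m <- if (length(stack$channels) < 3L)
    expand_stack_channels(stack, n_model) else stack
  cfg_m <- cfg
  cfg_m$n_channels <- n_model
  rows <- seq_len(stack$height)
  pairs <- pairs_from_region(stack_m, truth, rows, bands$train,
                             cfg$patch_size, train_stride)
  bundle <- mcgan_train(pairs, cfg_m)
  test_stack <- crop_stack(stack_m, rows, bands$test)
  test_truth <- crop_rgb(truth, rows, bands$test)
  pred <- colorize(bundle, test_stack, overlap = overlap)
  list(report = compute_metrics(pred, test_truth, sigma = metric_sigma),
       bundle = bundle, pred = pred, truth = test_truth,
       n_train_patches = length(pairs))
}

#' K-study: choose the number of time-domain features
#'
#' For each K in `k_range`, learns K features from the training band of the
#' non-radiative raster, unmixes feature images, trains the colorization
#' model on `[R_266, m_f1 ... m_fK]`, and evaluates SSIM (plus PSNR/RMSE)
#' on the held-out test band. `best_k` maximizes SSIM; a K whose clustering
#' or training fails is recorded as failed and excluded from the argmax
#' with a warning.
#'
#' At reduced scale (small patches, few epochs) a single training run's
#' SSIM fluctuates with the model seed by about as much as the true
#' between-K differences; `n_models` trains that many replicate models per
#' K (distinct seeds) and compares seed-averaged scores instead.
#'
#' @param nr_raster non-radiative [td_signal_raster].
#' @param r_raster radiative [td_signal_raster] (same field of view).
#' @param truth ground-truth [rgb_image].
#' @param k_range candidate cluster counts (default `2:6`).
#' @param cfg an [mcgan_config]; `n_channels` is overridden per K.
#' @param split train/val/test vertical-band fractions.
#' @param train_stride patch stride in the training band (default half a
#'   patch).
#' @param subset_fraction fraction of training-band pixels used for feature
#'   learning.
#' @param metric_sigma pre-metric blur (default 2).
#' @param seed seed for feature learning.
#' @param n_models replicate models trained per K (default 1); scores are
#'   averaged across replicates.
#' @param verbose print progress.
#' @return a `k_study_report`: data frame `results` (K, ssim, psnr_db,
#'   rmse, ssim_sd, converged), `best_k`, and the per-K [feature_set]s.
#' @export
run_k_study <- function(nr_raster, r_raster, truth, k_range = 2:6, cfg,
                        split = c(0.7, 0.1, 0.2),
                        train_stride = cfg$patch_size %/% 2L,
                        subset_fraction = 0.1, metric_sigma = 2,
                        seed = 1L, n_models = 1L, verbose = FALSE) {
  if (any(k_range < 2L) || any(k_range > 6L))
    stop("`k_range` must lie within [2, 6]")
  bands <- band_layout(nr_raster$height, nr_raster$width, cfg$patch_size, split)
  train_raster <- crop_raster(nr_raster, seq_len(nr_raster$height),
                              bands$train)
  rows <- data.frame()
  feature_sets <- list()
  for (K in k_range) {
    res <- tryCatch({
      fs <- learn_features(train_raster, K = K,
                           subset_fraction = subset_fraction, seed = seed)
      fi <- unmix(nr_raster, fs)
      r_win <- split_excitation_windows(r_raster)$EX266
      chans <- c(list(preprocess_channel(
                   extract_amplitude(r_raster, r_win, name = "R_266"))),
                 lapply(fi$images, preprocess_channel))
      stack <- channel_stack(chans)
      reps <- lapply(seq_len(n_models), function(r) {
        cfg_r <- cfg
        cfg_r$seed <- cfg$seed + 997L * (r - 1L)
        train_and_score(stack, truth, cfg_r, split, train_stride,
                        metric_sigma)$report
      })
      ssims <- vapply(reps, `[[`, numeric(1), "ssim")
      list(fs = fs, ssim = mean(ssims),
           psnr = mean(vapply(reps, `[[`, numeric(1), "psnr_db")),
           rmse = mean(vapply(reps, `[[`, numeric(1), "rmse")),
           ssim_sd = if (n_models > 1L) stats::sd(ssims) else NA_real_,
           ok = TRUE)
    }, error = function(e) {
      warning("K = ", K, " failed: ", conditionMessage(e))
      list(fs = NULL, ssim = NA_real_, psnr = NA_real_, rmse = NA_real_,
           ssim_sd = NA_real_, ok = FALSE)
    })
    feature_sets[[as.character(K)]] <- res$fs
    rows <- rbind(rows, data.frame(K = K, ssim = res$ssim,
                                   psnr_db = res$psnr, rmse = res$rmse,
                                   ssim_sd = res$ssim_sd,
                                   converged = res$ok))
    if (verbose)
      message(sprintf("K = %d: SSIM %.4f", K, res$ssim))
  }
  if (!any(rows$converged)) stop("every K failed")
  best_k <- rows$K[which.max(ifelse(rows$converged, rows$ssim, -Inf))]
  structure(list(results = rows, best_k = best_k,
                 feature_sets = feature_sets,
                 provenance = list(seed = seed, split = split,
                                   metric_sigma = metric_sigma,
                                   n_models = n_models, cfg = cfg)),
            class = "k_study_report")
}

#' @export
print.k_study_report <- function(x, ...) {
  cat("<k_study_report>\n")
  print(x$results, row.names = FALSE)
  cat("best K =", x$best_k, "\n")
  invisible(x)
}

#' C-study: exhaustive channel-combination search
#'
#' Trains one colorization model per non-empty subset of the channel array,
#' evaluates each on the held-out test band, ranks the subsets per metric
#' (1 = best; SSIM and PSNR higher-better, RMSE and LPIPS lower-better) and
#' aggregates ranks into a final ordering (mean per-metric rank, ties broken
#' by SSIM rank, then subset label; LPIPS joins the aggregate only when a
#' perceptual hook is supplied). Subsets smaller than three channels are
#' expanded to three by duplicating their last channel, mirroring the
#' target-side expansion rule. A subset whose training fails is flagged and
#' ranked last.
#'
#' @param stack the full channel array A as a [channel_stack] (e.g. from
#'   [build_channel_stack()]).
#' @param truth ground-truth [rgb_image] for the same field of view.
#' @param cfg an [mcgan_config]; `n_channels` is overridden per subset.
#' @param split,train_stride,metric_sigma as in [run_k_study()].
#' @param min_size smallest subset size (default 1).
#' @param lpips_fn optional perceptual metric hook (see
#'   [compute_metrics()]).
#' @param verbose print progress.
#' @return a `c_study_report`: data frame `results` with one row per subset
#'   (subset label, metrics, per-metric ranks, aggregate score, failure
#'   flag), sorted by aggregate score.
#' @export
run_c_study <- function(stack, truth, cfg, split = c(0.7, 0.1, 0.2),
                        train_stride = cfg$patch_size %/% 2L,
                        metric_sigma = 2, min_size = 1L, lpips_fn = NULL,
                        verbose = FALSE) {
  subsets <- enumerate_combinations(stack_names(stack), min_size)
  rows <- data.frame()
  for (si in seq_along(subsets)) {
    sub <- subsets[[si]]
    label <- paste(sub, collapse = ", ")
    res <- tryCatch({
      sc <- train_and_score(stack_subset(stack, sub), truth, cfg, split,
                            train_stride, metric_sigma)
      # perceptual hook applies to the blurred held-out pair
      lp <- if (is.null(lpips_fn)) NA_real_ else {
        bp <- blur_pair(sc$pred, sc$truth, metric_sigma)
        lpips_fn(bp$pred, bp$truth)
      }
      data.frame(subset = label, n_channels = length(sub),
                 ssim = sc$report$ssim, psnr_db = sc$report$psnr_db,
                 rmse = sc$report$rmse, lpips = lp, failed = FALSE)
    }, error = function(e) {
      warning("subset {", label, "} failed: ", conditionMessage(e))
      data.frame(subset = label, n_channels = length(sub),
                 ssim = NA_real_, psnr_db = NA_real_, rmse = NA_real_,
                 lpips = NA_real_, failed = TRUE)
    })
    rows <- rbind(rows, res)
    if (verbose)
      message(sprintf("[%d/%d] {%s}: SSIM %.4f", si, length(subsets),
                      label, res$ssim))
  }
  rows <- rank_combinations(rows, use_lpips = !is.null(lpips_fn))
  structure(list(results = rows,
                 provenance = list(split = split,
                                   metric_sigma = metric_sigma, cfg = cfg)),
            class = "c_study_report")
}

# per-metric ranks (failures last), aggregate score, final ordering
rank_combinations <- function(rows, use_lpips = FALSE) {
  n <- nrow(rows)
  rank_of <- function(values, higher_better) {
    key <- if (higher_better) -values else values
    key[is.na(key)] <- Inf  # failures rank last
    rank(key, ties.method = "average")
  }
  rows$rank_ssim <- rank_of(rows$ssim, TRUE)
  rows$rank_psnr <- rank_of(rows$psnr_db, TRUE)
  rows$rank_rmse <- rank_of(rows$rmse, FALSE)
  agg <- cbind(rows$rank_ssim, rows$rank_psnr, rows$rank_rmse)
  if (use_lpips) {
    rows$rank_lpips <- rank_of(rows$lpips, FALSE)
    agg <- cbind(agg, rows$rank_lpips)
  }
  rows$aggregate_score <- rowMeans(agg)
  ord <- order(rows$failed, rows$aggregate_score, rows$rank_ssim,
               rows$subset)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' @export
print.c_study_report <- function(x, ...) {
  cat(sprintf("<c_study_report> %d combination(s)\n", nrow(x$results)))
  print(utils::head(x$results, 10), row.names = FALSE)
  if (nrow(x$results) > 10) cat("...\n")
  invisible(x)
}

#' Write a study report to CSV and JSON
#'
#' Deterministic row order (the report's own ordering).
#'
#' @param report a `k_study_report` or `c_study_report`.
#' @param path_csv,path_json output paths (either may be `NULL` to skip).
#' @return `invisible(report)`.
#' @export
write_study_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv))
    utils::write.csv(report$results, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    payload <- list(results = report$results)
    if (!is.null(report$best_k)) payload$best_k <- report$best_k
    jsonlite::write_json(payload, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
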