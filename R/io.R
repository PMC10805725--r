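#' File formats
#'
#' One raster file per field of view: a compact binary container holding a
#' single JSON header line (dimensions, time step, excitation schedule)
#' followed by the little-endian float64 signal payload in pixel-major
#' order. Channel and RGB images travel as float TIFF (analysis) or 8-bit
#' PNG (display), with the channel name carried in a `<fov>_<CHANNEL>.tif`
#' filename convention. Feature sets are a JSON sidecar (metadata) plus a
#' float64 binary centroid payload. Phantom specs serialize to YAML.
#'
#' @name pars_io
NULL

#' Write a signal raster to a binary container file
#'
#' @param raster a [td_signal_raster].
#' @param path output file path (conventionally `.pars`).
#' @return `invisible(path)`. Reading the file back yields a bit-identical
#'   raster.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "td_signal_raster"))
  header <- jsonlite::toJSON(
    list(magic = "pars-raster-v1", height = raster$height,
         width = raster$width, n_samples = raster$n_samples,
         time_step_ns = raster$time_step_ns,
         schedule_label = raster$schedule$label,
         schedule_time_ns = raster$schedule$time_ns),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeBin(as.vector(raster$signals), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a signal raster written by [write_raster()]
#'
#' @param path file path.
#' @return a [td_signal_raster].
#' @export
read_raster <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- tryCatch(jsonlite::fromJSON(readLines(con, n = 1L)),
                     error = function(e) NULL)
  if (!identical(header$magic, "pars-raster-v1"))
    stop("not a pars raster container: ", path)
  n <- header$height * header$width * header$n_samples
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  td_signal_raster(
    array(v, c(header$height, header$width, header$n_samples)),
    header$time_step_ns,
    data.frame(label = header$schedule_label,
               time_ns = header$schedule_time_ns))
}

#' Write a channel image as float TIFF
#'
#' The filename follows `<prefix>_<CHANNEL>.tif`.
#'
#' @param img a [channel_image] with values in `[0, 1]`.
#' @param dir output directory.
#' @param prefix field-of-view prefix.
#' @return invisible path of the written file.
#' @export
write_channel_tiff <- function(img, dir, prefix = "fov") {
  stopifnot(inherits(img, "channel_image"))
  path <- file.path(dir, sprintf("%s_%s.tif", prefix, img$name))
  tiff::writeTIFF(clip01(img$values), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a channel image written by [write_channel_tiff()]
#'
#' @param path TIFF path; the channel name is recovered from the
#'   `<prefix>_<CHANNEL>.tif` convention.
#' @return a [channel_image].
#' @export
read_channel_tiff <- function(path) {
  v <- tiff::readTIFF(path)
  if (is.array(v) && length(dim(v)) == 3L) v <- v[, , 1]
  name <- sub("\\.tif$", "", sub("^[^_]*_", "", basename(path)))
  channel_image(v, name)
}

#' Write an RGB image as TIFF or PNG
#'
#' @param img an [rgb_image].
#' @param path output path; `.png` writes 8-bit PNG for display, anything
#'   else a 3-channel float TIFF.
#' @return invisible path.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(img$values, path)
  else
    tiff::writeTIFF(img$values, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read an RGB image from TIFF or PNG
#' @param path image path.
#' @return an [rgb_image].
#' @export
read_rgb <- function(path) {
  v <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(v)) == 3L && dim(v)[3] > 3L) v <- v[, , 1:3]
  rgb_image(clip01(v))
}

#' Serialize a feature set to JSON + binary centroids
#'
#' Writes `<path>.json` (K, metadata, sign convention) and `<path>.bin`
#' (float64 centroid matrix, column-major). The round trip is exact.
#'
#' @param fs a [feature_set].
#' @param path base path without extension.
#' @return invisible base path.
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  meta <- fs$meta
  meta$window <- as.integer(meta$window)
  jsonlite::write_json(
    list(magic = "pars-featureset-v1", K = fs$K, n_samples = fs$n_samples,
         sign_convention = "largest-magnitude element positive",
         meta = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(fs$feature_matrix), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a feature set written by [write_feature_set()]
#'
#' @param path base path without extension.
#' @return a [feature_set].
#' @export
read_feature_set <- function(path) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  if (!identical(hdr$magic, "pars-featureset-v1"))
    stop("not a feature-set sidecar: ", path)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = hdr$n_samples * hdr$K, size = 8L,
               endian = "little")
  feature_set(matrix(v, hdr$n_samples, hdr$K), meta = as.list(hdr$meta))
}

#' Write / read a phantom spec as YAML
#'
#' Only the scalar knobs are serialized (dimensions, tissue preset, noise,
#' baseline, sampling, seed); class geometry and shape templates are
#' reconstructed by [phantom_spec()] so specs stay small and readable.
#'
#' @param spec a [phantom_spec].
#' @param path YAML path.
#' @return invisible path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(list(height = spec$height, width = spec$width,
                        tissue = spec$tissue, noise_sd = spec$noise_sd,
                        baseline_level = spec$baseline_level,
                        n_samples = spec$n_samples,
                        time_step_ns = spec$time_step_ns,
                        seed = spec$seed),
                   path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(height = y$height, width = y$width, tissue = y$tissue,
               noise_sd = y$noise_sd, baseline_level = y$baseline_level,
               n_samples = y$n_samples, time_step_ns = y$time_step_ns,
               seed = y$seed)
}
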