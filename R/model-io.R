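# Model checkpoints: a JSON manifest (config, architecture, training
# history, parameter shapes) plus one float64 binary payload with every
# parameter tensor concatenated in manifest order.

flatten_params <- function(params) {
  out <- list()
  for (net in names(params))
    for (nm in names(params[[net]])) {
      p <- params[[net]][[nm]]
      out[[paste(net, nm, sep = ".")]] <-
        list(dim = if (is.matrix(p)) dim(p) else length(p),
             values = as.vector(p))
    }
  out
}

#' Save / load a model bundle
#'
#' Writes `<path>.json` (manifest) and `<path>.bin` (parameters); the round
#' trip restores the bundle exactly.
#'
#' @param bundle a [model_bundle].
#' @param path base path without extension.
#' @return invisible base path (`save`); a [model_bundle] (`load`).
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  fl <- flatten_params(bundle$params)
  manifest <- list(
    magic = "pars-mcgan-v1",
    cfg = unclass(bundle$cfg),
    g_arch = bundle$g_arch, d_arch = bundle$d_arch,
    history = bundle$history,
    params = lapply(fl, function(x) list(dim = x$dim)))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (x in fl) writeBin(x$values, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  man <- jsonlite::fromJSON(paste0(path, ".json"), simplifyDataFrame = TRUE)
  if (!identical(man$magic, "pars-mcgan-v1"))
    stop("not a model checkpoint: ", path)
  cfg <- structure(man$cfg, class = "mcgan_config")
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  params <- list(gAB = list(), gBA = list(), dA = list(), dB = list())
  for (key in names(man$params)) {
    d <- man$params[[key]]$dim
    v <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]] <-
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  g_arch <- man$g_arch; g_arch$c_enc <- as.integer(g_arch$c_enc)
  hist <- man$history
  structure(list(params = params, g_arch = g_arch, d_arch = man$d_arch,
                 cfg = cfg,
                 history = if (is.null(hist)) NULL else as.data.frame(hist)),
            class = "model_bundle")
}
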