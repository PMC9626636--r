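#' Save / load an AE--AR model checkpoint
#'
#' A checkpoint is a directory with a JSON manifest (config, scaler,
#' projector `A`, lift `B`, autoregression `r` and `z'`, the sign
#' convention) and a CSV weight container with every layer parameter written
#' at 17 significant digits -- enough for a bit-exact reload of doubles.
#'
#' @param model a trained (or untrained) `aear_model`.
#' @param dir checkpoint directory (created if needed).
#' @return invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "aear_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(model$config),
                   scaler = list(center = fmt17(model$scaler$center),
                                 scale = fmt17(model$scaler$scale),
                                 features = model$scaler$features),
                   sign = model$sign,
                   trained = model$trained,
                   A = fmt17(model$params$A), B = fmt17(model$params$B),
                   r = fmt17(model$params$r),
                   zprime = fmt17(model$params$zprime))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rows <- list()
  for (comp in c("enc", "dec")) {
    pl <- model$params[[comp]]
    for (i in seq_along(pl)) for (nm in names(pl[[i]])) {
      v <- pl[[i]][[nm]]
      d <- if (is.matrix(v)) dim(v) else c(length(v), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, layer = i, param = nm, nrow = d[1L], ncol = d[2L],
        values = paste(fmt17(v), collapse = " "))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "weights.csv"),
                   row.names = FALSE)
  invisible(dir)
}

fmt17 <- function(x) sprintf("%.17g", as.numeric(x))

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- do.call(aear_config, cfg[setdiff(names(cfg), character())])
  model <- suppressWarnings(build_model(config))
  model$scaler <- list(center = as.numeric(manifest$scaler$center),
                       scale = as.numeric(manifest$scaler$scale),
                       features = manifest$scaler$features)
  model$sign <- as.numeric(manifest$sign)
  model$trained <- isTRUE(manifest$trained)
  model$params$A <- matrix(as.numeric(manifest$A), 1L)
  model$params$B <- matrix(as.numeric(manifest$B), ncol = 1L)
  model$params$r <- as.numeric(manifest$r)
  model$params$zprime <- as.numeric(manifest$zprime)
  wt <- utils::read.csv(file.path(dir, "weights.csv"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(wt))) {
    v <- as.numeric(strsplit(wt$values[k], " ", fixed = TRUE)[[1L]])
    x <- if (wt$ncol[k] > 1L || wt$param[k] %in% c("W", "W1", "W2"))
      matrix(v, wt$nrow[k], wt$ncol[k]) else v
    model$params[[wt$component[k]]][[wt$layer[k]]][[wt$param[k]]] <- x
  }
  model
}
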