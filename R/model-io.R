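# Model checkpoints: one NPY file per parameter block plus a JSON sidecar
# carrying the orientation and training configuration.

#' Save an RBM model checkpoint
#'
#' Writes \code{<prefix>_W.npy}, \code{<prefix>_a.npy},
#' \code{<prefix>_b.npy}, \code{<prefix>_D.npy} and a JSON sidecar
#' \code{<prefix>.json} with the orientation and any extra configuration.
#'
#' @param model An [RBMModel-class].
#' @param prefix Output path prefix.
#' @param config Optional named list stored in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
saveRBMModel <- function(model, prefix, config = list()) {
  writeNpy(model@W, paste0(prefix, "_W.npy"))
  writeNpy(model@a, paste0(prefix, "_a.npy"))
  writeNpy(model@b, paste0(prefix, "_b.npy"))
  writeNpy(model@D, paste0(prefix, "_D.npy"))
  meta <- c(list(orientation = model@orientation,
                 nVisible = nVisible(model), m = nHidden(model)), config)
  json <- paste0("{", paste(sprintf('"%s": %s', names(meta),
    vapply(meta, function(v)
      if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15),
      "")), collapse = ", "), "}")
  writeLines(json, paste0(prefix, ".json"))
  invisible(paste0(prefix, ".json"))
}

#' Load an RBM model checkpoint
#'
#' @param prefix Path prefix used by [saveRBMModel()].
#' @return An [RBMModel-class].
#' @export
loadRBMModel <- function(prefix) {
  meta <- readLines(paste0(prefix, ".json"), warn = FALSE)
  orientation <- sub('.*"orientation": "([^"]+)".*', "\\1", paste(meta, collapse = ""))
  W <- readNpy(paste0(prefix, "_W.npy"))
  RBMModel(W = W,
           a = as.matrix(readNpy(paste0(prefix, "_a.npy"))),
           b = as.numeric(readNpy(paste0(prefix, "_b.npy"))),
           D = as.matrix(readNpy(paste0(prefix, "_D.npy"))),
           orientation = orientation)
}
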