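# Model persistence: a single JSON document holding per-class connection
# matrices, branch leaks, margins, dimensions and provenance (seed).

#' Write a trained model to JSON
#'
#' @param model a `dendnet_model`.
#' @param path output file path.
#' @param seed optional RNG seed to record alongside the model.
#' @export
write_dendnet_model <- function(model, path, seed = NULL) {
  doc <- list(
    format = "dendnet-model",
    version = 1L,
    d = model$d, k = model$k, n_classes = model$n_classes,
    delta = model$delta,
    seed = seed,
    trees = lapply(model$trees, function(tp) {
      lapply(tp, function(tr) list(
        W = unclass(tr$W)[, , drop = FALSE],
        zleak = tr$zleak))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_dendnet_model()]
#'
#' @param path JSON file path.
#' @return a `dendnet_model`.
#' @export
read_dendnet_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "dendnet-model"))
    stop("not a dendnet model file")
  trees <- lapply(seq_len(doc$n_classes), function(mu) {
    tp <- doc$trees[[mu]]
    lapply(tp, function(tr) {
      W <- do.call(rbind, lapply(tr$W, function(row) as.numeric(unlist(row))))
      list(W = W, zleak = as.numeric(unlist(tr$zleak)))
    })
  })
  structure(list(trees = trees, delta = as.numeric(unlist(doc$delta)),
                 d = doc$d, k = doc$k, n_classes = doc$n_classes),
            class = "dendnet_model")
}
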