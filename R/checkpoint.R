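#' Save a model checkpoint
#'
#' Serialises the weights, running statistics, architecture spec, class
#' ordering and preprocessing config into a single RDS container that
#' round-trips bit-exactly.
#'
#' @param model a [TwoStreamModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "TwoStreamModel"))
  saveRDS(list(format = "florafusion-checkpoint-1", spec = model@spec,
               params = model@params, state = model@state,
               frozen = model@frozen, classes = model@classes,
               preprocess = model@preprocess),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return the [TwoStreamModel-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable checkpoint '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "florafusion-checkpoint-1"))
    stop("not a florafusion checkpoint: ", path)
  new("TwoStreamModel", spec = obj$spec, params = obj$params,
      state = obj$state, frozen = obj$frozen, classes = obj$classes,
      preprocess = obj$preprocess)
}
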