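#' Save and load circuit checkpoints
#'
#' Checkpoints are written as RDS (R's structured binary serialisation),
#' which round-trips every weight bitwise: loading a checkpoint reproduces
#' forward passes exactly. Any of the package's model objects can be
#' checkpointed (`cann_circuit`, `cann_fit`, `cann_bank`,
#' `cann_convergent_fit`); architecture, variant and seeds travel with the
#' object.
#'
#' @param object Model object to persist.
#' @param path Destination file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  if (!inherits(object, c("cann_circuit", "cann_fit", "cann_bank",
                          "cann_convergent_fit"))) {
    abort("`object` is not a checkpointable model object.")
  }
  saveRDS(list(format = "cann-checkpoint", format_version = 1L,
               class = class(object)[1], object = object),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "cann-checkpoint")) {
    abort(sprintf("'%s' is not a circuit checkpoint.", path))
  }
  x$object
}
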