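#' Save and load a trained seed model container
#'
#' The container is a single binary file (R serialization) holding the
#' Potts model, the pointer prior, and training metadata, wrapped with a
#' format tag and a version number so stale or foreign files fail loudly
#' instead of being misread.
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` (may be `NULL`).
#' @param path output file.
#' @param meta named list of training hyperparameters / provenance.
#' @export
save_model <- function(model, prior, path, meta = list()) {
  if (!is.null(prior) && prior$L != model$L)
    stop("consistency error: model L=", model$L, " but prior L=", prior$L)
  obj <- list(format = "pottsalign-container", version = 1L,
              model = model, prior = prior, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @param prior_check optional `pointer_prior` to validate against the
#'   loaded model (its L must agree).
#' @return `load_model` returns `list(model, prior, meta)`.
#' @export
load_model <- function(path, prior_check = NULL) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("format error: ", path,
                                           " is not a pottsalign model container"))
  if (!is.list(obj) || !identical(obj$format, "pottsalign-container"))
    stop("format error: ", path, " is not a pottsalign model container")
  if (!identical(obj$version, 1L))
    stop("version mismatch: container version ", obj$version,
         " is not supported (expected 1)")
  if (!is.null(obj$prior) && obj$prior$L != obj$model$L)
    stop("consistency error: container model L=", obj$model$L,
         " but prior L=", obj$prior$L)
  if (!is.null(prior_check) && prior_check$L != obj$model$L)
    stop("consistency error: model L=", obj$model$L,
         " but provided prior has L=", prior_check$L)
  obj[c("model", "prior", "meta")]
}
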