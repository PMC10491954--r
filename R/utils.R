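# Internal numeric and plumbing helpers.

# log(sum(exp(v))) robust to -Inf entries
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# column-wise logsumexp of a matrix; returns length-ncol vector
log_col_sum_exp <- function(M) {
  D <- nrow(M); C <- ncol(M)
  mx <- M[cbind(max.col(t(M), ties.method = "first"), seq_len(C))]
  out <- mx + log(.colSums(exp(M - rep(mx, each = D)), D, C))
  out[!is.finite(mx)] <- -Inf
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.pa_log_env <- new.env(parent = emptyenv())
.pa_log_env$level <- "info"
.pa_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log verbosity
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly (so it can be restored).
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  old <- .pa_log_env$level
  .pa_log_env$level <- match.arg(level)
  invisible(old)
}

pa_log <- function(level, fmt, ...) {
  if (.pa_levels[[level]] >= .pa_levels[[.pa_log_env$level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
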