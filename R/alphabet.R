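#' Sequence alphabets with an explicit gap state
#'
#' Builds the symbol set used throughout the package. The gap character `-`
#' is an ordinary Potts state and is always the *last* state, so a protein
#' alphabet has q = 21 states (20 amino acids + gap) and an RNA alphabet has
#' q = 5 (ACGU + gap). A custom alphabet may be supplied for toy models;
#' its gap must also come last (it is appended if absent).
#'
#' @param kind one of `"protein"`, `"rna"`, `"custom"`.
#' @param symbols for `kind = "custom"`, a character vector of single
#'   characters; `-` is appended as the gap state if not already last.
#' @param t_to_u for RNA, map `T` to `U` on encoding (default `FALSE`;
#'   off by default to avoid silently rewriting data).
#' @return an object of class `pa_alphabet` with fields `symbols`, `q`,
#'   `kind`, `gap` (the gap index, always `q`).
#' @examples
#' ab <- make_alphabet("rna")
#' ab$q            # 5
#' encode_seq("ACGU", ab)
#' @export
make_alphabet <- function(kind = c("protein", "rna", "custom"),
                          symbols = NULL, t_to_u = FALSE) {
  kind <- match.arg(kind)
  symbols <- switch(kind,
    protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"),
    rna     = c("A", "C", "G", "U", "-"),
    custom  = {
      if (is.null(symbols)) stop("custom alphabet requires `symbols`")
      symbols <- as.character(symbols)
      if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
      if (!identical(symbols[length(symbols)], "-")) {
        if ("-" %in% symbols) stop("gap `-` must be the last symbol")
        symbols <- c(symbols, "-")
      }
      if (anyDuplicated(symbols)) stop("duplicated alphabet symbols")
      symbols
    })
  structure(list(symbols = symbols, q = length(symbols), kind = kind,
                 gap = length(symbols), t_to_u = isTRUE(t_to_u)),
            class = "pa_alphabet")
}

#' @export
print.pa_alphabet <- function(x, ...) {
  cat(sprintf("<pa_alphabet> kind=%s q=%d symbols=%s\n",
              x$kind, x$q, paste(x$symbols, collapse = "")))
  invisible(x)
}

#' Encode characters to alphabet indices
#'
#' @param x a single string or a character vector of single characters.
#' @param alphabet a [make_alphabet()] object.
#' @param context optional label used in error messages.
#' @return integer vector of 1-based state indices (gap = `alphabet$q`).
#' @export
encode_seq <- function(x, alphabet, context = "sequence") {
  chars <- if (length(x) == 1L && nchar(x) != 1L) strsplit(x, "")[[1]] else x
  if (alphabet$kind == "rna" && alphabet$t_to_u) {
    chars[chars == "T"] <- "U"
    chars[chars == "t"] <- "u"
  }
  idx <- match(chars, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("symbol error in %s: character '%s' at position %d is not in the %s alphabet",
                 context, chars[bad], bad, alphabet$kind))
  }
  idx
}

#' Decode alphabet indices back to a string
#'
#' @inheritParams encode_seq
#' @param idx integer vector of state indices.
#' @return a single string.
#' @export
decode_seq <- function(idx, alphabet) {
  stopifnot(all(idx >= 1L), all(idx <= alphabet$q))
  paste(alphabet$symbols[idx], collapse = "")
}
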