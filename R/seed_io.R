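#' Seed alignments: containers and parsers
#'
#' A seed MSA is the hand-curated family alignment the model is trained on.
#' Match columns are the L consensus columns; insert-state residues live in
#' runs attached to the L+1 inter-column boundaries (boundary 0 = before
#' column 1, boundary L = after column L). Two on-disk conventions are
#' supported:
#'
#' * **A2M**: uppercase letters and `-` are match states; lowercase letters
#'   are insert residues; `.` is insert-column padding and is dropped.
#' * **Stockholm**: the `#=GC RF` annotation marks match columns (any
#'   non-`.` character); residues in non-RF columns are insert residues.
#'
#' @name seed_io
NULL

new_seed_row <- function(id, match_symbols, insert_runs) {
  structure(list(id = id, match_symbols = as.integer(match_symbols),
                 insert_runs = insert_runs),
            class = "seed_row")
}

#' Construct a seed MSA object
#'
#' @param alphabet a [make_alphabet()] object.
#' @param rows list of seed rows (as produced by [read_seed()]).
#' @param weights per-row positive weights; defaults to 1.
#' @return an object of class `seed_msa` with fields `alphabet`, `L`,
#'   `rows`, `weights`.
#' @export
new_seed_msa <- function(alphabet, rows, weights = NULL) {
  if (length(rows) == 0L) stop("empty-seed error: no rows")
  Ls <- vapply(rows, function(r) length(r$match_symbols), integer(1))
  if (length(unique(Ls)) != 1L) stop("format error: ragged rows (unequal match-column counts)")
  L <- Ls[[1L]]
  if (L == 0L) stop("empty-seed error: zero match columns")
  if (is.null(weights)) weights <- rep(1, length(rows))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  structure(list(alphabet = alphabet, L = L, rows = rows,
                 weights = as.numeric(weights)),
            class = "seed_msa")
}

#' @export
print.seed_msa <- function(x, ...) {
  cat(sprintf("<seed_msa> %d rows, L=%d match columns, %s alphabet (q=%d), M_eff=%.2f\n",
              length(x$rows), x$L, x$alphabet$kind, x$alphabet$q, sum(x$weights)))
  invisible(x)
}

#' Matrix of match-column states of a seed MSA
#' @param msa a `seed_msa`.
#' @return integer matrix (rows x L), gap encoded as state q.
#' @export
seed_matrix <- function(msa) {
  do.call(rbind, lapply(msa$rows, function(r) r$match_symbols))
}

#' Reconstruct the unaligned sequence of a seed row
#'
#' Concatenates, in column order, the insert runs and the non-gap match
#' residues. Gap states contribute nothing, so the result is gapless.
#'
#' @param row a seed row.
#' @param msa the owning `seed_msa` (for L and the gap state).
#' @return integer vector of residue states (possibly length 0).
#' @export
reconstruct_row <- function(row, msa) {
  gap <- msa$alphabet$gap
  out <- integer(0)
  for (i in seq_len(msa$L)) {
    out <- c(out, row$insert_runs[[i]])
    if (row$match_symbols[i] != gap) out <- c(out, row$match_symbols[i])
  }
  c(out, row$insert_runs[[msa$L + 1L]])
}

uniquify_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  counts <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  dup <- counts > 1L
  pa_log("warn", "duplicate sequence ids; suffixing occurrence counters (%d affected)", sum(dup))
  ids[dup] <- sprintf("%s_%d", ids[dup], counts[dup])
  ids
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(trimws(lines), ">"))) return(Biostrings::BStringSet())
  Biostrings::readBStringSet(path, format = "fasta")
}

parse_a2m_row <- function(id, chars, alphabet) {
  gap <- alphabet$gap
  is_upper <- grepl("^[A-Z]$", chars)
  is_lower <- grepl("^[a-z]$", chars)
  bad <- !(is_upper | is_lower | chars %in% c("-", "."))
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("symbol error in row '%s' column %d: character '%s' is not valid A2M",
                 id, k, chars[k]))
  }
  match_mask <- is_upper | chars == "-"
  keep <- match_mask | is_lower  # '.' and other padding dropped silently
  L <- sum(match_mask)
  match_symbols <- integer(L)
  insert_runs <- rep(list(integer(0)), L + 1L)
  col <- 0L
  for (k in which(keep)) {
    ch <- chars[k]
    if (match_mask[k]) {
      col <- col + 1L
      match_symbols[col] <- if (ch == "-") gap else
        encode_seq(ch, alphabet, context = sprintf("row '%s' column %d", id, k))
    } else {
      insert_runs[[col + 1L]] <- c(insert_runs[[col + 1L]],
        encode_seq(toupper(ch), alphabet, context = sprintf("row '%s' column %d", id, k)))
    }
  }
  new_seed_row(id, match_symbols, insert_runs)
}

read_seed_a2m <- function(path, alphabet) {
  set <- read_fasta_raw(path)
  if (length(set) == 0L) stop("empty-seed error: no rows in ", path)
  ids <- uniquify_ids(names(set))
  rows <- lapply(seq_along(set), function(m) {
    parse_a2m_row(ids[m], strsplit(as.character(set[[m]]), "")[[1]], alphabet)
  })
  rows
}

read_seed_stockholm <- function(path, alphabet) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_ids <- character(0)
  rf <- ""
  for (ln in lines) {
    if (ln == "" || ln == "//") next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+RF\\s+", ln))
        rf <- paste0(rf, sub("^#=GC\\s+RF\\s+", "", ln))
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("format error: malformed Stockholm sequence line: ", ln)
    id <- parts[1L]
    if (is.null(seqs[[id]])) { seqs[[id]] <- ""; order_ids <- c(order_ids, id) }
    seqs[[id]] <- paste0(seqs[[id]], parts[2L])
  }
  if (length(seqs) == 0L) stop("empty-seed error: no rows in ", path)
  if (nchar(rf) == 0L) stop("format error: Stockholm seed lacks a #=GC RF annotation line")
  widths <- nchar(unlist(seqs))
  if (length(unique(widths)) != 1L || widths[1L] != nchar(rf))
    stop("format error: ragged rows (alignment widths disagree with RF)")
  rf_chars <- strsplit(rf, "")[[1]]
  match_cols <- rf_chars != "."
  gapchars <- c("-", ".", "_", "~")
  gap <- alphabet$gap
  rows <- lapply(order_ids, function(id) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    L <- sum(match_cols)
    match_symbols <- integer(L)
    insert_runs <- rep(list(integer(0)), L + 1L)
    col <- 0L
    for (k in seq_along(chars)) {
      ch <- chars[k]
      if (match_cols[k]) {
        col <- col + 1L
        match_symbols[col] <- if (ch %in% gapchars) gap else
          encode_seq(toupper(ch), alphabet, context = sprintf("row '%s' column %d", id, k))
      } else if (!(ch %in% gapchars)) {
        insert_runs[[col + 1L]] <- c(insert_runs[[col + 1L]],
          encode_seq(toupper(ch), alphabet, context = sprintf("row '%s' column %d", id, k)))
      }
    }
    new_seed_row(id, match_symbols, insert_runs)
  })
  rows
}

#' Read a seed alignment
#'
#' @param path file path.
#' @param format `"a2m"` or `"stockholm"`.
#' @param alphabet a [make_alphabet()] object (default protein).
#' @return a [new_seed_msa()] object; weights initialized to 1.
#' @export
read_seed <- function(path, format = c("a2m", "stockholm"),
                      alphabet = make_alphabet("protein")) {
  format <- match.arg(format)
  rows <- switch(format,
                 a2m = read_seed_a2m(path, alphabet),
                 stockholm = read_seed_stockholm(path, alphabet))
  msa <- new_seed_msa(alphabet, rows)
  empty <- vapply(msa$rows, function(r) length(reconstruct_row(r, msa)) == 0L, logical(1))
  if (any(empty))
    pa_log("warn", "%d seed row(s) reconstruct to an empty unaligned sequence: %s",
           sum(empty), paste(vapply(msa$rows[empty], `[[`, "", "id"), collapse = ", "))
  msa
}

#' Read unaligned query sequences from FASTA
#'
#' Sequences are uppercased on read (queries carry no match/insert case
#' semantics) and must contain no gap characters.
#'
#' @param path FASTA file.
#' @param alphabet a [make_alphabet()] object.
#' @return a list of records, each `list(id, seq, N)` with `seq` the encoded
#'   integer sequence; an empty FASTA yields an empty list.
#' @export
read_queries <- function(path, alphabet) {
  set <- read_fasta_raw(path)
  if (length(set) == 0L) return(list())
  ids <- uniquify_ids(names(set))
  lapply(seq_along(set), function(m) {
    s <- as.character(set[[m]])
    if (grepl("[-.]", s))
      stop(sprintf("input error: query '%s' contains gap characters", ids[m]))
    seq <- encode_seq(toupper(s), alphabet, context = sprintf("query '%s'", ids[m]))
    if (any(seq == alphabet$gap))
      stop(sprintf("input error: query '%s' contains gap characters", ids[m]))
    list(id = ids[m], seq = seq, N = length(seq))
  })
}

# Render one aligned result as an A2M string (uppercase matches, '-' gaps,
# lowercase insertions) or plain FASTA (insertions dropped).
render_alignment <- function(res, alphabet, format) {
  L <- length(res$x); N <- length(res$query)
  ncore <- if (length(res$n) == L + 2L) res$n[2:(L + 1L)] else res$n
  sym <- alphabet$symbols
  out <- character(0)
  n_prev <- 0L
  for (i in seq_len(L)) {
    if (res$x[i] == 1L) {
      ins <- if (ncore[i] - 1L >= n_prev + 1L) res$query[(n_prev + 1L):(ncore[i] - 1L)] else integer(0)
      if (format == "a2m" && length(ins)) out <- c(out, tolower(sym[ins]))
      out <- c(out, sym[res$query[ncore[i]]])
      n_prev <- ncore[i]
    } else {
      out <- c(out, "-")
    }
  }
  if (N > n_prev) {
    ins <- res$query[(n_prev + 1L):N]
    if (format == "a2m") out <- c(out, tolower(sym[ins]))
  }
  paste(out, collapse = "")
}

#' Write aligned results
#'
#' In A2M mode match states are written uppercase/`-` and unmatched query
#' residues appear lowercase between the flanking match columns, so reading
#' the file back with [read_seed()] recovers each (x, n) configuration
#' exactly. Plain FASTA mode drops insertions.
#'
#' @param results list of alignment results (each with fields `id`, `x`,
#'   `n`, `query`), e.g. from [align_sequences()].
#' @param path output file.
#' @param format `"a2m"` or `"fasta"`.
#' @param alphabet the alphabet the queries were encoded with.
#' @export
write_alignment <- function(results, path, format = c("a2m", "fasta"), alphabet) {
  format <- match.arg(format)
  Ls <- vapply(results, function(r) length(r$x), integer(1))
  if (length(unique(Ls)) > 1L)
    stop("internal error: results have inconsistent L")
  lines <- unlist(lapply(results, function(r)
    c(paste0(">", r$id), render_alignment(r, alphabet, format))))
  writeLines(lines, path)
  invisible(NULL)
}

#' Write a seed MSA in A2M format
#' @param msa a `seed_msa`.
#' @param path output file.
#' @export
write_seed <- function(msa, path) {
  sym <- msa$alphabet$symbols
  lines <- unlist(lapply(msa$rows, function(r) {
    out <- character(0)
    for (i in seq_len(msa$L)) {
      ins <- r$insert_runs[[i]]
      if (length(ins)) out <- c(out, tolower(sym[ins]))
      out <- c(out, if (r$match_symbols[i] == msa$alphabet$gap) "-" else sym[r$match_symbols[i]])
    }
    ins <- r$insert_runs[[msa$L + 1L]]
    if (length(ins)) out <- c(out, tolower(sym[ins]))
    c(paste0(">", r$id), paste(out, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(NULL)
}
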