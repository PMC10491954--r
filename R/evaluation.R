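#' DCA contact scores: Frobenius norm with average-product correction
#'
#' The score of a column pair (i, j) is the Frobenius norm of the zero-sum
#' gauged coupling block restricted to non-gap states, followed by the
#' average-product correction (APC): score minus row mean times column mean
#' over grand mean (means over off-diagonal pairs). Pairs closer than
#' `min_separation` are zeroed; scores are clipped at zero. The input is
#' re-gauged internally, so the scores are invariant under any gauge
#' transformation of the couplings.
#'
#' @param model a `potts_model`.
#' @param min_separation pairs with |i - j| < min_separation are zeroed
#'   (default 5, standard contact-prediction practice).
#' @return symmetric L x L matrix of class `contact_scores`.
#' @export
contact_scores <- function(model, min_separation = 5L) {
  model <- zero_sum_gauge(model)
  L <- model$L; q <- model$q
  ng <- seq_len(q - 1L)
  F <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    F[i, j] <- sqrt(sum(model$J[i, j, ng, ng]^2))
    F[j, i] <- F[i, j]
  }
  if (L > 1L) {
    off <- !diag(TRUE, L)
    rm_ <- rowSums(F) / (L - 1L)
    gm <- sum(F[off]) / (L * (L - 1L))
    S <- F - outer(rm_, rm_) / gm
    if (!is.finite(gm) || gm == 0) S <- F
  } else S <- F
  diag(S) <- 0
  S[abs(row(S) - col(S)) < min_separation] <- 0
  S <- pmax(S, 0)
  structure(S, class = c("contact_scores", class(S)),
            min_separation = min_separation)
}

#' Positive predictive value curve of ranked contact predictions
#'
#' Pairs (i < j) with nonzero eligibility are ranked by score (descending;
#' ties broken lexicographically by (i, j)); PPV(k) is the fraction of true
#' contacts among the top k.
#'
#' @param scores a [contact_scores()] matrix (or any symmetric matrix).
#' @param contacts two-column matrix / data frame of true contact pairs
#'   (1-based, unordered).
#' @param k_max number of ranks to report (truncated with a warning if it
#'   exceeds the number of scored pairs).
#' @return data frame with columns `k`, `i`, `j`, `score`, `is_contact`,
#'   `ppv`.
#' @export
ppv_curve <- function(scores, contacts, k_max = NULL) {
  contacts <- as.matrix(contacts)
  if (nrow(contacts) == 0L) stop("contacts must be nonempty")
  L <- nrow(scores)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  ord <- order(-scores[ut], ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  if (is.null(k_max)) k_max <- nrow(ut)
  if (k_max > nrow(ut)) {
    warning("k_max exceeds the number of scored pairs; truncating to ", nrow(ut))
    k_max <- nrow(ut)
  }
  ut <- ut[seq_len(k_max), , drop = FALSE]
  ckey <- paste(pmin(contacts[, 1L], contacts[, 2L]),
                pmax(contacts[, 1L], contacts[, 2L]))
  hit <- paste(ut[, 1L], ut[, 2L]) %in% ckey
  data.frame(k = seq_len(k_max), i = ut[, 1L], j = ut[, 2L],
             score = scores[ut], is_contact = hit,
             ppv = cumsum(hit) / seq_len(k_max))
}

#' Proximity of a generated alignment to the seed
#'
#' For each generated row, the minimum normalized Hamming distance over
#' match columns (gap counted as a state) to any seed row; reports the
#' per-row distances and their mean.
#'
#' @param generated,seed `seed_msa` objects with equal L.
#' @param metric distance metric (only `"mean_nearest_hamming"`).
#' @return a `proximity_report`: `per_row`, `mean`, `metric`.
#' @export
msa_proximity <- function(generated, seed, metric = "mean_nearest_hamming") {
  metric <- match.arg(metric)
  if (generated$L != seed$L)
    stop("input error: L mismatch (", generated$L, " vs ", seed$L, ")")
  G <- seed_matrix(generated); S <- seed_matrix(seed)
  L <- ncol(G)
  per_row <- vapply(seq_len(nrow(G)), function(g) {
    d <- rowSums(sweep(S, 2L, G[g, ], "!=")) / L
    min(d)
  }, numeric(1))
  structure(list(per_row = per_row, mean = mean(per_row), metric = metric),
            class = "proximity_report")
}

#' @export
print.proximity_report <- function(x, ...) {
  cat(sprintf("<proximity_report> %s: mean=%.4f over %d rows (range %.4f..%.4f)\n",
              x$metric, x$mean, length(x$per_row), min(x$per_row), max(x$per_row)))
  invisible(x)
}
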