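#' Pointer trajectory of a seed row
#'
#' For an aligned row, the pointer n_i gives the position in the row's own
#' unaligned (gapless) sequence of the residue matched at column i; at gap
#' columns the pointer carries the last matched position. Walking the
#' columns left to right, a counter over the unaligned sequence advances by
#' the insert-run length at each boundary and by one at each non-gap match.
#' The returned vector has length L+2 with the boundary values n_0 = 0 and
#' n_{L+1} = N+1 fixed. Consequently the pointer difference
#' dn_{i,j} = n_j - n_i counts the matched plus inserted residues consumed
#' between columns i and j; gaps contribute nothing.
#'
#' @param row a seed row.
#' @param msa the owning `seed_msa`.
#' @return integer vector of length L+2 (entries n_0, n_1, ..., n_L, n_{L+1}).
#' @export
pointer_trajectory <- function(row, msa) {
  L <- msa$L; gap <- msa$alphabet$gap
  n <- integer(L + 2L)
  counter <- 0L
  for (i in seq_len(L)) {
    counter <- counter + length(row$insert_runs[[i]])
    if (row$match_symbols[i] != gap) {
      counter <- counter + 1L
      n[i + 1L] <- counter
    } else {
      n[i + 1L] <- n[i]
    }
  }
  counter <- counter + length(row$insert_runs[[L + 1L]])
  n[L + 2L] <- counter + 1L
  n
}

pair_table <- function(L, pair_set = "all_pairs", band = NULL) {
  idx <- 0:(L + 1L)
  pairs <- do.call(rbind, lapply(idx[-length(idx)], function(i) {
    j <- idx[idx > i]
    cbind(i = rep(i, length(j)), j = j)
  }))
  if (identical(pair_set, "banded")) {
    stopifnot(!is.null(band), band >= 1)
    pa_log("info", "pointer prior restricted to banded pair set (W=%d)", band)
    pairs <- pairs[pairs[, "j"] - pairs[, "i"] <= band, , drop = FALSE]
  }
  pairs
}

#' Empirical pointer-difference priors
#'
#' For each pair (i, j) with 0 <= i < j <= L+1 in the pair set, the weighted
#' histogram of dn_{i,j} = n_j - n_i over the seed rows, smoothed by a
#' floor: the normalized histogram is mixed with a uniform floor mass so
#' every probability on the support \{0, ..., dn_max\} is at least the
#' floor epsilon (unseen pointer differences remain reachable at finite
#' inverse temperature). dn_max is the largest observed difference plus
#' `slack`. Values outside the support are assigned the floor mass.
#' Boundary pairs involving positions 0 and L+1 constrain leading and
#' trailing unmatched residues.
#'
#' @param msa a `seed_msa` (weights are used unless `unweighted = TRUE`).
#' @param floor smoothing floor epsilon; default
#'   `1 / (10 * (M_eff + support size))` per pair.
#' @param pair_set `"all_pairs"` (default) or `"banded"`.
#' @param band band width W when `pair_set = "banded"`.
#' @param slack extra support beyond the largest observed difference.
#' @param unweighted ignore seed weights when accumulating histograms.
#' @return object of class `pointer_prior`.
#' @export
fit_pointer_prior <- function(msa, floor = NULL, pair_set = c("all_pairs", "banded"),
                              band = NULL, slack = 2L, unweighted = FALSE) {
  pair_set <- match.arg(pair_set)
  if (!is.null(floor)) stopifnot(floor > 0)
  L <- msa$L
  w <- if (unweighted) rep(1, length(msa$rows)) else msa$weights
  M_eff <- sum(w)
  traj <- do.call(rbind, lapply(msa$rows, pointer_trajectory, msa = msa))
  pairs <- pair_table(L, pair_set, band)
  tab <- vector("list", nrow(pairs))
  names(tab) <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    dn <- traj[, j + 1L] - traj[, i + 1L]
    dmax <- max(dn) + slack
    counts <- numeric(dmax + 1L)
    for (m in seq_along(dn)) counts[dn[m] + 1L] <- counts[dn[m] + 1L] + w[m]
    p <- counts / sum(counts)
    K <- dmax + 1L
    eps <- if (is.null(floor)) 1 / (10 * (M_eff + K)) else floor
    if (K * eps >= 1) stop("floor too large for support of pair (", i, ",", j, ")")
    p <- (1 - K * eps) * p + eps
    tab[[k]] <- list(logp = log(p), log_eps = log(eps))
  }
  structure(list(L = L, pairs = pairs, tab = tab, pair_set = pair_set,
                 band = band, slack = slack, floor = floor,
                 unweighted = unweighted, M_eff = M_eff),
            class = "pointer_prior")
}

#' @export
print.pointer_prior <- function(x, ...) {
  cat(sprintf("<pointer_prior> L=%d, %d pairs (%s), slack=%d\n",
              x$L, nrow(x$pairs), x$pair_set, x$slack))
  invisible(x)
}

#' Log prior probability of a pointer difference
#'
#' @param prior a `pointer_prior`.
#' @param i,j pair indices, 0 <= i < j <= L+1 (0 and L+1 are boundaries).
#' @param dn integer vector of pointer differences.
#' @return numeric vector of log probabilities; out-of-support values get
#'   the pair's floor mass; pairs outside the stored pair set return 0.
#' @export
prior_logp <- function(prior, i, j, dn) {
  entry <- prior$tab[[paste(i, j, sep = "|")]]
  if (is.null(entry)) return(rep(0, length(dn)))
  out <- rep(entry$log_eps, length(dn))
  ok <- dn >= 0L & dn <= length(entry$logp) - 1L
  out[ok] <- entry$logp[dn[ok] + 1L]
  out
}
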