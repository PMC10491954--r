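#' Sequence reweighting by match-column identity
#'
#' Standard DCA reweighting: the weight of row m is 1 over the number of
#' rows (including itself) whose fractional identity with m over the L
#' match columns (gap counted as a state) is at least `identity_threshold`.
#' The effective sample size is M_eff = sum of weights.
#'
#' @param msa a `seed_msa`.
#' @param identity_threshold fraction in (0, 1].
#' @return numeric vector of weights, one per row.
#' @export
compute_weights <- function(msa, identity_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  S <- seed_matrix(msa)
  M <- nrow(S); L <- ncol(S)
  sim <- matrix(0, M, M)
  for (i in seq_len(L)) sim <- sim + outer(S[, i], S[, i], "==")
  neighbors <- rowSums(sim / L >= identity_threshold)
  1 / neighbors
}

#' Weighted one- and two-site frequencies of a seed MSA
#'
#' Frequencies are the weighted empirical counts over match columns mixed
#' with the uniform distribution: f = (1 - lambda) f_data + lambda * uniform,
#' applied consistently to the one-site table `f1` (L x q) and the two-site
#' table `f2` (L x L x q x q). Diagonal blocks of `f2` hold `f1` on their
#' own diagonal so that marginalizing `f2[i, j, , ]` over the second state
#' returns `f1[i, ]` for every j.
#'
#' @param msa a `seed_msa` with weights set (see [compute_weights()]).
#' @param pseudocount mixing fraction lambda in [0, 1).
#' @return a `seed_statistics` object: `f1`, `f2`, `M_eff`.
#' @export
empirical_statistics <- function(msa, pseudocount = 0) {
  stopifnot(pseudocount >= 0, pseudocount < 1)
  S <- seed_matrix(msa)
  w <- msa$weights / sum(msa$weights)
  M <- nrow(S); L <- ncol(S); q <- msa$alphabet$q
  lam <- pseudocount

  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) {
    tab <- tapply(w, factor(S[, i], levels = seq_len(q)), sum)
    f1[i, ] <- ifelse(is.na(tab), 0, tab)
  }
  f1 <- (1 - lam) * f1 + lam / q

  f2 <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) {
      f2[i, i, , ] <- diag(f1[i, ], q, q)
    } else if (i < j) {
      tab <- matrix(0, q, q)
      for (m in seq_len(M)) tab[S[m, i], S[m, j]] <- tab[S[m, i], S[m, j]] + w[m]
      tab <- (1 - lam) * tab + lam / (q * q)
      f2[i, j, , ] <- tab
      f2[j, i, , ] <- t(tab)
    }
  }
  structure(list(f1 = f1, f2 = f2, M_eff = sum(msa$weights)),
            class = "seed_statistics")
}
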