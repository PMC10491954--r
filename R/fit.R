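#' Fit a seed model: Potts parameters plus pointer-difference priors
#'
#' The one-stop trainer. From a seed MSA it computes identity-based
#' sequence weights, fits the Potts (DCA) model by regularized
#' pseudo-likelihood maximization, and learns the empirical
#' pointer-difference priors that encode the seed's insertion and gap
#' statistics. The returned object is everything needed to align queries.
#'
#' @param seed a `seed_msa` (see [read_seed()]) .
#' @param identity_threshold reweighting identity threshold (default 0.8).
#' @param lambda_h,lambda_J PLM L2 penalties (default 0.01).
#' @param prior_floor smoothing floor for the priors (default chosen from
#'   M_eff, see [fit_pointer_prior()]).
#' @param pair_set `"all_pairs"` or `"banded"` prior pair set.
#' @param band band width when `pair_set = "banded"`.
#' @param slack extra prior support beyond the largest observed difference.
#' @param unweighted_prior accumulate prior histograms without seed weights.
#' @param max_iter,grad_tol PLM optimizer controls.
#' @return an object of class `seed_model` with components `potts`
#'   (a `potts_model` in zero-sum gauge), `prior` (a `pointer_prior`),
#'   `weights`, `M_eff`, `alphabet`, `L` and `call`.
#' @seealso [predict.seed_model()] to align queries, [simulate.seed_model()]
#'   to Gibbs-sample from the fitted Potts model, [contact_scores()].
#' @examples
#' fam <- make_planted_family(L = 6, q = 4, n_seed = 80, n_queries = 2, seed = 1)
#' fit <- fit_seed_model(fam$seed_msa)
#' fit
#' @export
fit_seed_model <- function(seed, identity_threshold = 0.8,
                           lambda_h = 0.01, lambda_J = 0.01,
                           prior_floor = NULL, pair_set = "all_pairs",
                           band = NULL, slack = 2L, unweighted_prior = FALSE,
                           max_iter = 400L, grad_tol = 1e-5) {
  seed$weights <- compute_weights(seed, identity_threshold)
  potts <- fit_plm(seed, lambda_h = lambda_h, lambda_J = lambda_J,
                   max_iter = max_iter, grad_tol = grad_tol)
  prior <- fit_pointer_prior(seed, floor = prior_floor, pair_set = pair_set,
                             band = band, slack = slack,
                             unweighted = unweighted_prior)
  structure(list(potts = potts, prior = prior, weights = seed$weights,
                 M_eff = sum(seed$weights), alphabet = seed$alphabet,
                 L = seed$L, call = match.call()),
            class = "seed_model")
}

#' @export
print.seed_model <- function(x, ...) {
  cat("Seed model (Potts + pointer-difference priors)\n")
  cat(sprintf("  L = %d match columns, q = %d states (%s alphabet)\n",
              x$L, x$alphabet$q, x$alphabet$kind))
  cat(sprintf("  M_eff = %.1f effective sequences\n", x$M_eff))
  cat(sprintf("  prior: %d pairs (%s)\n", nrow(x$prior$pairs), x$prior$pair_set))
  invisible(x)
}

#' @export
summary.seed_model <- function(object, n_top = 5L, ...) {
  cs <- contact_scores(object$potts, min_separation = 2L)
  ut <- which(upper.tri(cs), arr.ind = TRUE)
  ord <- order(-cs[ut])
  top <- ut[ord[seq_len(min(n_top, nrow(ut)))], , drop = FALSE]
  out <- list(L = object$L, q = object$alphabet$q, M_eff = object$M_eff,
              n_prior_pairs = nrow(object$prior$pairs),
              top_pairs = data.frame(i = top[, 1L], j = top[, 2L],
                                     score = cs[top]))
  class(out) <- "summary.seed_model"
  out
}

#' @export
print.summary.seed_model <- function(x, ...) {
  cat(sprintf("Seed model: L=%d q=%d M_eff=%.1f prior pairs=%d\n",
              x$L, x$q, x$M_eff, x$n_prior_pairs))
  cat("Top coupling pairs (Frobenius-APC):\n")
  print(x$top_pairs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.seed_model <- function(object, ...) {
  list(h = object$potts$h, J = object$potts$J)
}

#' Align query sequences with a fitted seed model
#'
#' @param object a [fit_seed_model()] object.
#' @param queries list of query records (see [read_queries()]) or bare
#'   encoded integer vectors.
#' @param schedule an [anneal_schedule()].
#' @param seed RNG seed for reproducible message initialization.
#' @param ... unused.
#' @return list of `query_alignment` results (see [anneal_align()]).
#' @export
predict.seed_model <- function(object, queries, schedule = anneal_schedule(),
                               seed = NULL, ...) {
  align_sequences(object$potts, object$prior, queries, schedule, seed)
}

#' Gibbs-sample aligned sequences from a fitted seed model
#'
#' @param object a `seed_model`.
#' @param nsim number of sequences.
#' @param seed RNG seed.
#' @param burn_in,thin sampler controls (see [gibbs_sample()]).
#' @param ... unused.
#' @return a `seed_msa` of sampled sequences.
#' @export
simulate.seed_model <- function(object, nsim = 1L, seed = NULL,
                                burn_in = 200L, thin = 5L, ...) {
  mat <- gibbs_sample(object$potts, nsim, burn_in = burn_in, thin = thin,
                      seed = seed)
  msa_from_matrix(mat, object$alphabet,
                  ids = sprintf("sampled_%d", seq_len(nsim)))
}

#' Plot the contact-score map of a fitted seed model
#'
#' @param x a `seed_model`.
#' @param min_separation passed to [contact_scores()].
#' @param ... passed to [graphics::image()].
#' @export
plot.seed_model <- function(x, min_separation = 2L, ...) {
  cs <- contact_scores(x$potts, min_separation = min_separation)
  graphics::image(seq_len(x$L), seq_len(x$L), unclass(cs),
                  xlab = "column i", ylab = "column j",
                  main = "Frobenius-APC contact scores", ...)
  invisible(x)
}
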