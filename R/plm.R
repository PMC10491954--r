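#' Fit a Potts model by pseudo-likelihood maximization
#'
#' Maximizes the weighted, L2-regularized pseudo-likelihood of the seed's
#' match columns: for every site i the conditional
#' P(S_i = a | S_\\i) is proportional to exp(h_i(a) + sum_{j != i} J_ij(a, S_j)),
#' and the objective is the weight-averaged sum over sites of the
#' log-conditionals minus per-parameter L2 penalties. Sites are optimized
#' independently (asymmetric PLM) with L-BFGS-B and the couplings are then
#' symmetrized by averaging, J_ij <- (J_ij + t(J_ji)) / 2. The result is
#' returned in the zero-sum gauge.
#'
#' @param msa a `seed_msa` with at least 2 rows; weights should be set
#'   (see [compute_weights()]).
#' @param lambda_h,lambda_J per-parameter L2 penalties on fields and
#'   couplings (defaults 0.01, standard plmDCA practice).
#' @param max_iter iteration cap per site (logged if reached).
#' @param grad_tol termination threshold on the gradient sup-norm.
#' @return a `potts_model` in zero-sum gauge, with attribute `"plm_fit"`
#'   holding per-site convergence diagnostics.
#' @export
fit_plm <- function(msa, lambda_h = 0.01, lambda_J = 0.01,
                    max_iter = 400L, grad_tol = 1e-5) {
  S <- seed_matrix(msa)
  M <- nrow(S); L <- ncol(S); q <- msa$alphabet$q
  if (M < 2L) stop("fit_plm requires at least 2 seed rows")
  w <- msa$weights / sum(msa$weights)

  # dense one-hot design, M x (L*q)
  X <- matrix(0, M, L * q)
  X[cbind(rep(seq_len(M), L), (rep(seq_len(L), each = M) - 1L) * q + as.vector(S))] <- 1

  Jhat <- array(0, dim = c(L, L, q, q))  # Jhat[i, j, a, b]: a at i (conditioned site)
  h <- matrix(0, L, q)
  conv <- integer(L)
  for (i in seq_len(L)) {
    other <- setdiff(seq_len(L), i)
    cols <- as.vector(vapply(other, function(j) (j - 1L) * q + seq_len(q), integer(q)))
    Xo <- X[, cols, drop = FALSE]
    yi <- S[, i]
    dat <- list(Xo = Xo, yi = yi, w = w, q = q, n_other = L - 1L,
                lambda_h = lambda_h, lambda_J = lambda_J)
    par0 <- numeric(q + q * (L - 1L) * q)
    fit <- tryCatch(
      stats::optim(par0,
                   fn = function(p) plm_site_objective(p, dat)$f,
                   gr = function(p) plm_site_objective(p, dat)$g,
                   method = "L-BFGS-B",
                   control = list(maxit = max_iter, pgtol = grad_tol, factr = 1e4)),
      error = function(e) stop("numerical error in PLM at site ", i, ": ",
                               conditionMessage(e)))
    if (fit$convergence == 1L)
      pa_log("warn", "PLM site %d hit the iteration cap (%d)", i, max_iter)
    conv[i] <- fit$convergence
    h[i, ] <- fit$par[seq_len(q)]
    Jm <- matrix(fit$par[-seq_len(q)], q, q * (L - 1L))
    for (k in seq_along(other))
      Jhat[i, other[k], , ] <- Jm[, ((k - 1L) * q + 1L):(k * q)]
  }

  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    K <- (Jhat[i, j, , ] + t(Jhat[j, i, , ])) / 2
    J[i, j, , ] <- K
    J[j, i, , ] <- t(K)
  }
  model <- zero_sum_gauge(new_potts_model(msa$alphabet, h, J))
  attr(model, "plm_fit") <- list(convergence = conv,
                                 lambda_h = lambda_h, lambda_J = lambda_J)
  model
}

# Negative regularized pseudo-log-likelihood and gradient for one site.
# par = c(h_i (q), vec of q x ((L-1) q) coupling matrix); dat holds the
# one-hot design over the other sites (Xo), the site's states (yi), the
# normalized weights and penalties.
plm_site_objective <- function(par, dat) {
  q <- dat$q
  M <- length(dat$yi)
  h <- par[seq_len(q)]
  Jm <- matrix(par[-seq_len(q)], q, q * dat$n_other)
  E <- dat$Xo %*% t(Jm)
  E <- sweep(E, 2L, h, "+")
  mx <- apply(E, 1L, max)
  lse <- mx + log(rowSums(exp(E - mx)))
  ll <- E[cbind(seq_len(M), dat$yi)] - lse
  f <- -sum(dat$w * ll) + dat$lambda_h * sum(h^2) + dat$lambda_J * sum(Jm^2)
  P <- exp(E - lse)
  R <- P
  R[cbind(seq_len(M), dat$yi)] <- R[cbind(seq_len(M), dat$yi)] - 1
  R <- R * dat$w
  gh <- colSums(R) + 2 * dat$lambda_h * h
  gJ <- t(R) %*% dat$Xo + 2 * dat$lambda_J * Jm
  list(f = f, g = c(gh, as.vector(gJ)))
}
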