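#' Potts (DCA) model over aligned sequences
#'
#' Fields `h` (L x q) and couplings `J` (L x L x q x q) define the energy
#' H(S) = -sum_i h_i(S_i) - sum_{i<j} J_ij(S_i, S_j) of an aligned sequence
#' S of length L over q states (gap is the q-th state). `J` is stored
#' pair-symmetric, J[i,j,a,b] = J[j,i,b,a], with zero diagonal blocks.
#'
#' @param alphabet a [make_alphabet()] object.
#' @param h L x q field matrix.
#' @param J L x L x q x q coupling array.
#' @param gauge gauge label; `"zero_sum"` after [zero_sum_gauge()].
#' @return object of class `potts_model`.
#' @export
new_potts_model <- function(alphabet, h, J, gauge = "none") {
  L <- nrow(h); q <- ncol(h)
  stopifnot(q == alphabet$q, identical(dim(J), c(L, L, q, q)))
  structure(list(alphabet = alphabet, L = L, q = q, h = h, J = J, gauge = gauge),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- sum(apply(abs(x$J), c(1, 2), max) > 1e-12) / 2
  cat(sprintf("<potts_model> L=%d q=%d gauge=%s nonzero coupling pairs=%d\n",
              x$L, x$q, x$gauge, nz))
  invisible(x)
}

#' Convert a Potts model to the zero-sum gauge
#'
#' The zero-sum (Ising) gauge removes the reparametrization freedom of the
#' Potts energy: after conversion every coupling block sums to zero along
#' each state index and every field sums to zero over states. Energies of
#' any two sequences keep the same difference.
#'
#' @param model a `potts_model`.
#' @return the gauged `potts_model`.
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h; J <- model$J
  h2 <- h
  J2 <- array(0, dim = dim(J))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      K <- J[i, j, , ]
      rm_ <- rowMeans(K); cm_ <- colMeans(K); gm <- mean(K)
      J2[i, j, , ] <- K - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + gm
      h2[i, ] <- h2[i, ] + (rm_ - gm)
    }
  }
  h2 <- h2 - rowMeans(h2)
  new_potts_model(model$alphabet, h2, J2, gauge = "zero_sum")
}

#' Apply an arbitrary gauge shift (testing aid)
#'
#' Shifts h_i(a) -> h_i(a) + u_i(a) - sum_j v_ij(a) and
#' J_ij(a,b) -> J_ij(a,b) + v_ij(a) + v_ji(b) leaves all energy
#' *differences* unchanged; here a random valid shift is generated.
#'
#' @param model a `potts_model`.
#' @param magnitude scale of the random shift.
#' @return a `potts_model` equivalent to `model` up to an additive constant.
#' @export
random_gauge_shift <- function(model, magnitude = 1) {
  L <- model$L; q <- model$q
  J <- model$J; h <- model$h
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i >= j) next
    vi <- stats::runif(q, -magnitude, magnitude)  # depends on a at site i
    vj <- stats::runif(q, -magnitude, magnitude)
    J[i, j, , ] <- J[i, j, , ] + outer(vi, rep(1, q)) + outer(rep(1, q), vj)
    J[j, i, , ] <- t(J[i, j, , ])
    h[i, ] <- h[i, ] - vi
    h[j, ] <- h[j, ] - vj
  }
  new_potts_model(model$alphabet, h, J, gauge = "shifted")
}

#' Potts energy of an aligned state
#'
#' Builds the aligned string S with S_i = A[n_i] where x_i = 1 and gap
#' elsewhere, then returns H(S) = -sum_i h_i(S_i) - sum_{i<j} J_ij(S_i,S_j).
#'
#' @param model a `potts_model`.
#' @param state an alignment state: list with `x` (0/1, length L), `n`
#'   (length L+2 pointer vector including boundaries), `query` (encoded
#'   integer sequence).
#' @return the scalar energy H.
#' @export
energy <- function(model, state) {
  N <- length(state$query)
  if (!is_feasible(state$x, state$n, N))
    stop("contract error: infeasible alignment state passed to energy()")
  S <- aligned_states(model, state$x, state$n, state$query)
  potts_energy_of(model, S)
}

# aligned integer states S_i from (x, n); n includes boundaries n_0, n_{L+1}
aligned_states <- function(model, x, n, query) {
  L <- model$L
  ncore <- n[2:(L + 1L)]
  ifelse(x == 1L, query[pmax(ncore, 1L)], model$alphabet$gap)
}

potts_energy_of <- function(model, S) {
  L <- model$L
  e <- -sum(model$h[cbind(seq_len(L), S)])
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L)
    e <- e - model$J[i, j, S[i], S[j]]
  e
}
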