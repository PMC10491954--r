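# Shared fixture builders and independent oracles for the test suite.

toy_alphabet <- function(q = 4L)
  make_alphabet("custom",
                symbols = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(q - 1L)])

# seed MSA from A2M-formatted strings, via a temp file (exercises the parser)
msa_from_a2m <- function(rows, alphabet = make_alphabet("protein"),
                         ids = sprintf("s%d", seq_along(rows))) {
  path <- withr::local_tempfile(fileext = ".a2m", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  read_seed(path, "a2m", alphabet)
}

# random Potts model with couplings on all pairs
random_potts <- function(L, q, scale = 0.5, seed = 1) {
  set.seed(seed)
  h <- matrix(runif(L * q, -scale, scale), L, q)
  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    K <- matrix(runif(q * q, -scale, scale), q, q)
    J[i, j, , ] <- K; J[j, i, , ] <- t(K)
  }
  new_potts_model(toy_alphabet(q), h, J)
}

# independent nested-loop Potts energy (deliberately naive)
naive_energy <- function(model, S) {
  e <- 0
  L <- model$L
  for (i in seq_len(L)) e <- e - model$h[i, S[i]]
  for (i in seq_len(L)) for (j in seq_len(L)) if (i < j)
    e <- e - model$J[i, j, S[i], S[j]]
  e
}

# exact single-node marginals of a chain MRF over the aligner's joint
# (x, n) states, by transfer-matrix forward-backward in log space;
# independent of the package's message-passing code.
chain_exact_marginals <- function(graph, beta) {
  D <- graph$D; L <- graph$L
  node <- beta * graph$node_base + graph$node_mask
  psi <- list()
  for (e in graph$edges) {
    if (e$j != e$i + 1L) stop("chain oracle requires consecutive edges only")
    psi[[e$i]] <- beta * e$psi + e$mask
  }
  fwd <- matrix(-Inf, D, L); bwd <- matrix(-Inf, D, L)
  fwd[, 1L] <- node[, 1L]
  for (i in 2:L) {
    for (s in seq_len(D))
      fwd[s, i] <- node[s, i] + logsumexp_vec(fwd[, i - 1L] + psi[[i - 1L]][, s])
  }
  bwd[, L] <- 0
  for (i in (L - 1L):1L) {
    for (s in seq_len(D))
      bwd[s, i] <- logsumexp_vec(bwd[, i + 1L] + node[, i + 1L] + psi[[i]][s, ])
  }
  B <- fwd + bwd
  apply(B, 2L, function(v) { v <- v - max(v); p <- exp(v); p / sum(p) })
}

logsumexp_vec <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
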