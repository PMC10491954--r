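#' Alignment states, feasibility and the alignment objective
#'
#' A query A of length N is aligned to the L model columns by a pair of
#' vectors: match indicators x (x_i = 1 if column i holds a query residue,
#' 0 if it is a gap) and pointers n (n_i = position in A matched at column
#' i; at gap columns n_i carries the last matched position). Boundaries are
#' fixed: n_0 = 0 and n_{L+1} = N + 1. A state is feasible when matched
#' pointers are strictly increasing within 1..N and gap columns carry.
#' Only the L <= N case is supported.
#'
#' @name alignment_state
NULL

#' Feasibility of an (x, n) configuration
#'
#' @param x 0/1 vector of length L.
#' @param n integer pointer vector of length L+2 including the boundary
#'   entries n_0 and n_{L+1}.
#' @param N query length.
#' @return `TRUE` iff the configuration is feasible.
#' @export
is_feasible <- function(x, n, N) {
  L <- length(x)
  if (length(n) != L + 2L) return(FALSE)
  if (n[1L] != 0L || n[L + 2L] != N + 1L) return(FALSE)
  if (any(n < 0L) || any(n > N + 1L)) return(FALSE)
  for (i in seq_len(L)) {
    if (x[i] == 1L) {
      if (!(n[i + 1L] > n[i]) || n[i + 1L] < 1L || n[i + 1L] > N) return(FALSE)
    } else {
      if (n[i + 1L] != n[i]) return(FALSE)
    }
  }
  n[L + 2L] > n[L + 1L]
}

#' Number of feasible alignment states
#'
#' Closed form: summing over the number of gap columns g, there are
#' choose(L, g) gap placements and choose(N, L - g) increasing pointer
#' assignments.
#'
#' @param L model length.
#' @param N query length.
#' @return the count (numeric, may be large).
#' @export
count_feasible <- function(L, N) {
  g <- 0:L
  sum(choose(L, g) * choose(N, L - g))
}

#' Log objective of the alignment problem
#'
#' Returns -beta * H(x, n) + beta * sum over the prior's pair set of
#' log P_ij(n_j - n_i). The intractable normalization is an additive
#' constant and is omitted.
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` (or `NULL` for no prior term).
#' @param state list with `x`, `n` (length L+2), `query`.
#' @param beta inverse temperature.
#' @return scalar log objective.
#' @export
log_objective <- function(model, prior, state, beta = 1) {
  H <- energy(model, state)
  beta * (-H + prior_logscore(prior, state$n))
}

# sum of log prior terms over the stored pair set, given the full pointer
# vector (length L+2, boundaries included)
prior_logscore <- function(prior, n) {
  if (is.null(prior)) return(0)
  s <- 0
  for (k in seq_len(nrow(prior$pairs))) {
    i <- prior$pairs[k, 1L]; j <- prior$pairs[k, 2L]
    s <- s + prior_logp(prior, i, j, n[j + 1L] - n[i + 1L])
  }
  s
}

#' Build the alignment factor graph for one query
#'
#' Variables are the joint (x_i, n_i) states of each column, a domain of
#' 2N + 1 states ordered match-first, pointer ascending (the decode
#' tie-break order). Node factors hold the fields, plus the boundary prior
#' terms P_{0,i}(n_i) and P_{i,L+1}(N + 1 - n_i) since n_0 and n_{L+1} are
#' fixed. Pair factors carry exp(beta J_ij(S_i, S_j)) P_ij(n_j - n_i)^beta;
#' consecutive-column factors additionally carry the hard feasibility
#' indicator. All potentials are stored on the log scale at beta = 1 and
#' scaled by beta at run time (masks are kept separate).
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` or `NULL`.
#' @param query encoded integer query sequence (no gaps).
#' @param chain_only drop all non-consecutive pair factors (used to check
#'   exactness of message passing on chain graphs).
#' @return an `align_graph` list.
#' @export
build_align_graph <- function(model, prior, query, chain_only = FALSE) {
  L <- model$L; N <- length(query); q <- model$q
  if (N < L) stop("input error: query length N=", N, " is smaller than the model length L=",
                  L, "; only the L <= N case is supported")
  xs <- c(rep(1L, N), rep(0L, N + 1L))
  ns <- c(seq_len(N), 0:N)
  D <- length(xs)
  sigma <- ifelse(xs == 1L, query[pmax(ns, 1L)], q)

  node_base <- matrix(0, D, L)
  for (i in seq_len(L)) {
    node_base[, i] <- model$h[i, sigma]
    if (!is.null(prior)) {
      node_base[, i] <- node_base[, i] +
        prior_logp(prior, 0L, i, ns) +
        prior_logp(prior, i, L + 1L, N + 1L - ns)
    }
  }
  node_mask <- matrix(0, D, L)
  node_mask[xs == 0L & ns > 0L, 1L] <- -Inf  # column 1 follows n_0 = 0

  dn_mat <- outer(ns, ns, function(a, b) b - a)  # rows s_i, cols s_j
  feas_mask <- matrix(-Inf, D, D)
  Xj <- matrix(xs, D, D, byrow = TRUE)           # x-component of s_j
  allow <- (Xj == 1L & dn_mat > 0L) | (Xj == 0L & dn_mat == 0L)
  feas_mask[allow] <- 0

  edges <- list()
  has_prior_pair <- function(i, j) !is.null(prior) && !is.null(prior$tab[[paste(i, j, sep = "|")]])
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    consec <- (j == i + 1L)
    if (chain_only && !consec) next
    coupled <- max(abs(model$J[i, j, , ])) > 0
    if (!consec && !coupled && !has_prior_pair(i, j)) next
    psi <- matrix(model$J[i, j, , ][cbind(rep(sigma, D), rep(sigma, each = D))], D, D)
    if (has_prior_pair(i, j))
      psi <- psi + matrix(prior_logp(prior, i, j, as.vector(dn_mat)), D, D)
    edges[[length(edges) + 1L]] <-
      list(i = i, j = j, psi = psi, mask = if (consec) feas_mask else NULL)
  }
  const <- if (!is.null(prior)) prior_logp(prior, 0L, L + 1L, N + 1L) else 0

  structure(list(L = L, N = N, D = D, xs = xs, ns = ns, sigma = sigma,
                 node_base = node_base, node_mask = node_mask,
                 edges = edges, const = const, feas_mask = feas_mask,
                 model = model, prior = prior, query = query),
            class = "align_graph")
}

#' Initialize a message-passing state
#'
#' Messages start uniform plus a small seeded random perturbation (default
#' amplitude 1e-3) to break symmetry reproducibly.
#'
#' @param graph an [build_align_graph()] object.
#' @param beta initial inverse temperature.
#' @param damping damping factor in [0, 1) applied on the probability scale.
#' @param noise amplitude of the symmetry-breaking perturbation.
#' @param seed RNG seed for the perturbation (`NULL` = use current RNG).
#' @return an environment of class `mp_state`.
#' @export
mp_state_init <- function(graph, beta, damping = 0.5, noise = 1e-3, seed = NULL) {
  E <- length(graph$edges)
  D <- graph$D
  ndir <- 2L * E
  from <- integer(ndir); to <- integer(ndir); edge_of <- integer(ndir); rev_of <- integer(ndir)
  for (e in seq_len(E)) {
    from[2L * e - 1L] <- graph$edges[[e]]$i; to[2L * e - 1L] <- graph$edges[[e]]$j
    from[2L * e] <- graph$edges[[e]]$j;      to[2L * e] <- graph$edges[[e]]$i
    edge_of[c(2L * e - 1L, 2L * e)] <- e
    rev_of[2L * e - 1L] <- 2L * e; rev_of[2L * e] <- 2L * e - 1L
  }
  incoming <- lapply(seq_len(graph$L), function(i) which(to == i))
  inc_less_rev <- lapply(seq_len(ndir), function(d)
    setdiff(incoming[[from[d]]], rev_of[d]))
  MSG <- with_seed(seed, {
    m <- matrix(stats::runif(D * max(ndir, 1L), 0, noise), D, max(ndir, 1L))
    log(sweep(exp(m), 2L, colSums(exp(m)), "/"))
  })
  if (ndir == 0L) MSG <- matrix(0, D, 0L)
  mp <- new.env(parent = emptyenv())
  mp$graph <- graph; mp$damping <- damping
  mp$MSG <- MSG; mp$from <- from; mp$to <- to; mp$edge_of <- edge_of
  mp$rev_of <- rev_of; mp$incoming <- incoming; mp$inc_less_rev <- inc_less_rev
  mp$sweeps <- 0L; mp$residual <- Inf
  class(mp) <- "mp_state"
  mp_set_beta(mp, beta)
  mp
}

#' Set the inverse temperature of a message-passing state
#' @param mp an `mp_state`.
#' @param beta new inverse temperature (>= 0).
#' @export
mp_set_beta <- function(mp, beta) {
  g <- mp$graph
  mp$beta <- beta
  mp$node_pot <- beta * g$node_base + g$node_mask
  mp$Psi <- lapply(g$edges, function(e) {
    P <- beta * e$psi
    if (!is.null(e$mask)) P <- P + e$mask
    P
  })
  mp$Psi_t <- lapply(mp$Psi, t)  # reverse-direction orientation
  invisible(mp)
}

#' One round-robin sweep of all directed messages
#'
#' Updates every directed message once, with damping, in a fixed order
#' (optionally reversed). Returns the residual: the maximum absolute
#' message change on the probability scale.
#'
#' @param mp an `mp_state`.
#' @param order `"forward"` or `"reverse"` update order.
#' @return the sweep residual (non-negative scalar).
#' @export
mp_sweep <- function(mp, order = c("forward", "reverse")) {
  order <- match.arg(order)
  g <- mp$graph
  ndir <- ncol(mp$MSG)
  idx <- seq_len(ndir)
  if (order == "reverse") idx <- rev(idx)
  D <- g$D
  resid <- 0
  for (d in idx) {
    i <- mp$from[d]; j <- mp$to[d]; e <- mp$edge_of[d]
    inc <- mp$inc_less_rev[[d]]
    pre <- mp$node_pot[, i]
    if (length(inc))
      pre <- pre + .rowSums(mp$MSG[, inc, drop = FALSE], D, length(inc))
    P <- if (d %% 2L == 1L) mp$Psi[[e]] else mp$Psi_t[[e]]  # rows = sender states
    raw <- log_col_sum_exp(P + pre)
    z <- logsumexp(raw)
    if (!is.finite(z))
      stop("numerical error: message ", i, "->", j, " has no admissible state")
    raw <- raw - z
    pold <- exp(mp$MSG[, d])
    pnew <- (1 - mp$damping) * exp(raw) + mp$damping * pold
    if (anyNA(pnew))
      stop("numerical error: NaN in message ", i, "->", j)
    resid <- max(resid, max(abs(pnew - pold)))
    mp$MSG[, d] <- log(pnew)
  }
  mp$sweeps <- mp$sweeps + 1L
  mp$residual <- resid
  resid
}

#' Current node beliefs
#'
#' @param mp an `mp_state`.
#' @param log return log beliefs (default) or probabilities.
#' @return D x L matrix of (log) beliefs, columns normalized.
#' @export
mp_beliefs <- function(mp, log = TRUE) {
  g <- mp$graph
  B <- mp$node_pot
  for (i in seq_len(g$L)) {
    inc <- mp$incoming[[i]]
    if (length(inc)) B[, i] <- B[, i] + rowSums(mp$MSG[, inc, drop = FALSE])
    B[, i] <- B[, i] - logsumexp(B[, i])
  }
  if (log) B else exp(B)
}

#' Annealing schedule for the aligner
#'
#' @param beta_start,beta_max first and last inverse temperature.
#' @param growth multiplicative growth factor per annealing step (> 1).
#' @param max_sweeps sweep cap at each beta.
#' @param tol residual tolerance declaring convergence at a beta.
#' @param damping message damping factor.
#' @param noise symmetry-breaking initialization amplitude.
#' @return an `anneal_schedule` list.
#' @export
anneal_schedule <- function(beta_start = 0.1, beta_max = 5, growth = 1.05,
                            max_sweeps = 100L, tol = 1e-4, damping = 0.5,
                            noise = 1e-3) {
  stopifnot(beta_start > 0, growth > 1, beta_max >= beta_start)
  betas <- beta_start * growth^(0:ceiling(log(beta_max / beta_start) / log(growth)))
  betas[betas > beta_max] <- beta_max
  betas <- unique(betas)
  structure(list(betas = betas, max_sweeps = as.integer(max_sweeps),
                 tol = tol, damping = damping, noise = noise),
            class = "anneal_schedule")
}

# exact chain DP over log beliefs; returns the feasible path maximizing the
# summed log beliefs, ties broken by preferring matches then smaller
# pointers (the state enumeration order).
decode_beliefs <- function(logb, graph) {
  D <- graph$D; L <- graph$L
  Tmask <- is.finite(graph$feas_mask)  # Tmask[s, s'] : s at column i, s' at i+1
  V <- matrix(-Inf, D, L)
  V[, L] <- logb[, L]
  if (L > 1L) for (i in (L - 1L):1L) {
    nxt <- V[, i + 1L]
    best <- vapply(seq_len(D), function(s) {
      v <- nxt[Tmask[s, ]]
      if (length(v)) max(v) else -Inf
    }, numeric(1))
    V[, i] <- logb[, i] + best
  }
  start_ok <- graph$xs == 1L | graph$ns == 0L
  cand <- which(start_ok)
  path <- integer(L)
  path[1L] <- cand[which.max(V[cand, 1L])]
  if (L > 1L) for (i in 2:L) {
    cand <- which(Tmask[path[i - 1L], ])
    path[i] <- cand[which.max(V[cand, i])]
  }
  list(x = graph$xs[path],
       n = c(0L, graph$ns[path], graph$N + 1L))
}

#' Decode a feasible alignment from message-passing beliefs
#'
#' Maximizes the sum of per-column log beliefs over feasible states by an
#' exact dynamic program along the column chain, so the output is feasible
#' regardless of message-passing convergence. Ties are broken by
#' preferring a match (x_i = 1) and then the smallest pointer.
#'
#' @param mp an `mp_state`.
#' @return list with `x` (length L) and `n` (length L+2, boundaries fixed).
#' @export
decode <- function(mp) {
  decode_beliefs(mp_beliefs(mp), mp$graph)
}

#' Local refinement of an alignment state by coordinate ascent
#'
#' Greedy ascent on the true log objective over single-column and
#' adjacent-column-pair moves (match/gap flips and pointer changes, with
#' gap-carry repair), iterated to a local optimum. Used to polish decoded
#' message-passing states; never decreases the objective.
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` or `NULL`.
#' @param query encoded integer query.
#' @param x,n a feasible state (n of length L+2).
#' @param window move width: 1 (single columns) or 2 (adds adjacent pairs).
#' @return list with refined `x`, `n` and the achieved `objective`.
#' @export
refine_state <- function(model, prior, query, x, n, window = 2L) {
  L <- model$L; N <- length(query)
  obj <- function(x, n) log_objective(model, prior, list(x = x, n = n, query = query))
  best <- obj(x, n)
  recarry <- function(x, n, from) {
    j <- from
    while (j <= L && x[j] == 0L) { n[j + 1L] <- n[j]; j <- j + 1L }
    n
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(L)) {
      lo <- n[i]
      for (p in c(NA, if (lo < N) (lo + 1L):N else integer(0))) {
        x2 <- x; n2 <- n
        if (is.na(p)) { x2[i] <- 0L; n2[i + 1L] <- lo }
        else { x2[i] <- 1L; n2[i + 1L] <- p }
        n2 <- recarry(x2, n2, i + 1L)
        if (!is_feasible(x2, n2, N)) next
        v <- obj(x2, n2)
        if (v > best + 1e-12) { x <- x2; n <- n2; best <- v; improved <- TRUE }
      }
    }
    if (window >= 2L && L >= 2L) for (i in seq_len(L - 1L)) {
      lo <- n[i]
      for (p in c(NA, if (lo < N) (lo + 1L):N else integer(0))) {
        ni <- if (is.na(p)) lo else p
        for (r in c(NA, if (ni < N) (ni + 1L):N else integer(0))) {
          x2 <- x; n2 <- n
          x2[i] <- if (is.na(p)) 0L else 1L
          n2[i + 1L] <- ni
          if (is.na(r)) { x2[i + 1L] <- 0L; n2[i + 2L] <- ni }
          else { x2[i + 1L] <- 1L; n2[i + 2L] <- r }
          n2 <- recarry(x2, n2, i + 2L)
          if (!is_feasible(x2, n2, N)) next
          v <- obj(x2, n2)
          if (v > best + 1e-12) { x <- x2; n <- n2; best <- v; improved <- TRUE }
        }
      }
    }
  }
  list(x = x, n = n, objective = best)
}

# clamp columns one at a time by belief confidence, re-converging after
# each clamp (decimation); mutates mp; returns nothing useful beyond mp
run_decimation <- function(mp, schedule) {
  g <- mp$graph
  clamped <- rep(FALSE, g$L)
  for (round in seq_len(g$L)) {
    B <- mp_beliefs(mp, log = FALSE)
    conf <- apply(B, 2L, max); conf[clamped] <- -1
    i <- which.max(conf)
    s <- which.max(B[, i])
    mask <- rep(-Inf, g$D); mask[s] <- 0
    mp$graph$node_mask[, i] <- mp$graph$node_mask[, i] + mask
    clamped[i] <- TRUE
    mp_set_beta(mp, mp$beta)
    for (sw in seq_len(schedule$max_sweeps))
      if (mp_sweep(mp) <= schedule$tol) break
  }
  invisible(mp)
}

#' Align one query by annealed message passing
#'
#' Runs loopy sum-product message passing on the alignment factor graph,
#' iteratively increasing the inverse temperature beta so the beliefs
#' concentrate on the objective's maximizer. The final beliefs are decoded
#' to a feasible state; a decimation pass (clamping columns one at a time
#' by belief confidence at the final beta, the classic message-passing
#' decimation scheme) provides a second candidate, and both are polished
#' by [refine_state()]; the state with the higher objective is returned.
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` or `NULL`.
#' @param query encoded integer query (length N >= L).
#' @param schedule an [anneal_schedule()].
#' @param seed RNG seed (message initialization); fixed seed gives
#'   bit-identical output.
#' @param id result identifier.
#' @param decimate run the decimation pass (default `TRUE`).
#' @param refine polish decoded states with [refine_state()] (default `TRUE`).
#' @return a `query_alignment`: `id`, `x`, `n`, `query`, `H` (Potts energy),
#'   `prior_logscore`, `log_objective` (at beta = 1), and a per-beta
#'   `diagnostics` data frame (sweeps used, final residual, converged flag).
#' @export
anneal_align <- function(model, prior, query, schedule = anneal_schedule(),
                         seed = NULL, id = "query", decimate = TRUE,
                         refine = TRUE) {
  graph <- build_align_graph(model, prior, query)
  mp <- mp_state_init(graph, beta = schedule$betas[1L],
                      damping = schedule$damping, noise = schedule$noise,
                      seed = seed)
  diag_rows <- vector("list", length(schedule$betas))
  for (k in seq_along(schedule$betas)) {
    mp_set_beta(mp, schedule$betas[k])
    sw <- 0L; resid <- Inf
    while (sw < schedule$max_sweeps) {
      resid <- mp_sweep(mp)
      sw <- sw + 1L
      if (resid <= schedule$tol) break
    }
    if (resid > schedule$tol)
      pa_log("warn", "MP did not converge at beta=%.4g (residual %.3g); continuing",
             schedule$betas[k], resid)
    diag_rows[[k]] <- data.frame(beta = schedule$betas[k], sweeps = sw,
                                 residual = resid, converged = resid <= schedule$tol)
  }
  cand <- list(decode(mp))
  if (decimate) {
    run_decimation(mp, schedule)
    cand[[2L]] <- decode(mp)
  }
  pick <- function(st) {
    st$query <- query
    if (refine) {
      r <- refine_state(model, prior, query, st$x, st$n)
      st$x <- r$x; st$n <- r$n
    }
    st
  }
  cand <- lapply(cand, pick)
  vals <- vapply(cand, function(st)
    log_objective(model, prior, st, beta = 1), numeric(1))
  st <- cand[[which.max(vals)]]
  H <- energy(model, st)
  pls <- prior_logscore(prior, st$n)
  structure(list(id = id, x = st$x, n = st$n, query = query, N = length(query),
                 H = H, prior_logscore = pls, log_objective = -H + pls,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "query_alignment")
}

#' @export
print.query_alignment <- function(x, ...) {
  cat(sprintf("<query_alignment> %s: L=%d N=%d matches=%d H=%.4f prior=%.4f\n",
              x$id, length(x$x), x$N, sum(x$x), x$H, x$prior_logscore))
  invisible(x)
}

#' Exhaustive alignment oracle
#'
#' Enumerates every feasible (x, n) configuration in the decode tie-break
#' order and returns the maximizer of [log_objective()]. Intended as an
#' exact reference for small instances.
#'
#' @inheritParams anneal_align
#' @param beta inverse temperature of the objective (the argmax is
#'   beta-invariant; kept for score reporting).
#' @param cap refuse instances with more feasible states than this.
#' @return a `query_alignment` (diagnostics field absent).
#' @export
exhaustive_align <- function(model, prior, query, beta = 1, cap = 2e6,
                             id = "query") {
  L <- model$L; N <- length(query)
  if (N < L) stop("input error: N < L is unsupported")
  cnt <- count_feasible(L, N)
  if (cnt > cap)
    stop("state-space cap exceeded: ", format(cnt, big.mark = ","),
         " feasible states > cap ", format(cap, big.mark = ","))
  best <- new.env(parent = emptyenv())
  best$val <- -Inf; best$x <- NULL; best$n <- NULL
  x <- integer(L); n <- integer(L)
  recurse <- function(i, n_prev) {
    if (i > L) {
      st <- list(x = x, n = c(0L, n, N + 1L), query = query)
      v <- log_objective(model, prior, st, beta = beta)
      if (v > best$val) { best$val <- v; best$x <- x; best$n <- st$n }
      return(invisible(NULL))
    }
    # matches first, pointers ascending, then the gap (tie-break order)
    if (n_prev < N) for (p in (n_prev + 1L):N) {
      # feasible completion needs N - p >= remaining matches possible; always
      # completable with gaps, so no pruning required for correctness
      x[i] <<- 1L; n[i] <<- p
      recurse(i + 1L, p)
    }
    x[i] <<- 0L; n[i] <<- n_prev
    recurse(i + 1L, n_prev)
  }
  recurse(1L, 0L)
  st <- list(x = best$x, n = best$n, query = query)
  H <- energy(model, st)
  pls <- prior_logscore(prior, st$n)
  structure(list(id = id, x = best$x, n = best$n, query = query, N = N,
                 H = H, prior_logscore = pls, log_objective = -H + pls,
                 diagnostics = NULL),
            class = "query_alignment")
}

#' Sample a random feasible alignment state (testing aid)
#'
#' Uniform over gap counts, then uniform over gap placements and pointer
#' subsets (not uniform over all states; adequate for randomized checks).
#'
#' @param L,N model and query lengths.
#' @return list with `x`, `n` (length L+2).
#' @export
random_feasible_state <- function(L, N) {
  gmin <- max(0L, L - N)
  g <- sample(gmin:L, 1L)
  gap_cols <- if (g > 0L) sort(sample(seq_len(L), g)) else integer(0)
  x <- rep(1L, L); x[gap_cols] <- 0L
  m <- L - g
  ptrs <- if (m > 0L) sort(sample(seq_len(N), m)) else integer(0)
  n <- integer(L); prev <- 0L; k <- 0L
  for (i in seq_len(L)) {
    if (x[i] == 1L) { k <- k + 1L; prev <- ptrs[k] }
    n[i] <- prev
  }
  list(x = x, n = c(0L, n, N + 1L))
}

#' Align a set of queries
#'
#' @param model a `potts_model`.
#' @param prior a `pointer_prior` or `NULL`.
#' @param queries list of query records (`list(id, seq, N)`, as returned by
#'   [read_queries()]) or a list of bare integer vectors.
#' @param schedule an [anneal_schedule()].
#' @param seed base RNG seed; query k uses `seed + k - 1`.
#' @return list of `query_alignment` results.
#' @export
align_sequences <- function(model, prior, queries, schedule = anneal_schedule(),
                            seed = NULL) {
  lapply(seq_along(queries), function(k) {
    qr <- queries[[k]]
    if (is.list(qr)) {
      anneal_align(model, prior, qr$seq, schedule,
                   seed = if (is.null(seed)) NULL else seed + k - 1L, id = qr$id)
    } else {
      anneal_align(model, prior, qr, schedule,
                   seed = if (is.null(seed)) NULL else seed + k - 1L,
                   id = paste0("query_", k))
    }
  })
}
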