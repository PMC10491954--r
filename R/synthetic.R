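#' Planted Potts models, Gibbs sampling and indel corruption
#'
#' The synthetic generator produces complete test families with known
#' ground truth: a planted Potts model (known coupled pairs), a seed MSA
#' Gibbs-sampled from it (gap characters arise naturally from the model's
#' gap state), and unaligned queries obtained by deleting gaps and
#' injecting geometric-length insertions, with the true (x, n) alignment
#' recorded for every query.
#'
#' @name synthetic
NULL

#' Build a planted Potts model
#'
#' Fields are i.i.d. uniform in [-field_strength, field_strength]; when
#' `gap_rate` is given, the gap-state field of every column is set so the
#' single-site gap probability is approximately `gap_rate`. Couplings are
#' nonzero only on the listed pairs, with a two-group block pattern of
#' entries +/- `coupling_strength` over the non-gap states (inducing
#' detectable covariation). The model is returned in zero-sum gauge.
#'
#' @param L number of columns.
#' @param q number of states (gap included as the q-th state).
#' @param pairs two-column matrix of coupled pairs (i < j).
#' @param coupling_strength,field_strength parameter scales.
#' @param gap_rate target single-site gap probability (`NULL` = the gap
#'   field is drawn like any other state).
#' @param seed RNG seed.
#' @return a `potts_model` (attribute `"planted_pairs"` holds the pairs).
#' @export
make_planted_model <- function(L, q, pairs, coupling_strength = 1,
                               field_strength = 1, gap_rate = NULL,
                               seed = NULL) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, all(pairs[, 1L] < pairs[, 2L]),
            all(pairs[, 2L] <= L), !anyDuplicated(paste(pairs[, 1L], pairs[, 2L])))
  # use a prefix of the amino-acid alphabet so fixture files are readable
  # as protein A2M/FASTA by the standard tooling
  alphabet <- make_alphabet("custom",
    symbols = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(q - 1L)])
  with_seed(seed, {
    h <- matrix(stats::runif(L * q, -field_strength, field_strength), L, q)
    if (!is.null(gap_rate)) {
      stopifnot(gap_rate > 0, gap_rate < 1)
      for (i in seq_len(L))
        h[i, q] <- log(gap_rate / (1 - gap_rate)) + logsumexp(h[i, seq_len(q - 1L)])
    }
    J <- array(0, dim = c(L, L, q, q))
    if (coupling_strength != 0 && nrow(pairs) > 0L) {
      grp <- (seq_len(q - 1L) - 1L) %% 2L
      K0 <- matrix(0, q, q)
      K0[seq_len(q - 1L), seq_len(q - 1L)] <-
        ifelse(outer(grp, grp, "=="), coupling_strength, -coupling_strength)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        J[i, j, , ] <- K0
        J[j, i, , ] <- t(K0)
      }
    }
    model <- zero_sum_gauge(new_potts_model(alphabet, h, J))
    attr(model, "planted_pairs") <- pairs
    model
  })
}

#' Gibbs-sample aligned sequences from a Potts model
#'
#' Single-site heat-bath updates, one full sweep over the L sites per
#' iteration; samples are taken after `burn_in` sweeps at the given
#' thinning.
#'
#' @param model a `potts_model`.
#' @param n_samples number of aligned sequences to return.
#' @param burn_in discarded initial sweeps.
#' @param thin sweeps between retained samples.
#' @param seed RNG seed.
#' @return integer matrix (n_samples x L) of state indices.
#' @export
gibbs_sample <- function(model, n_samples, burn_in = 200L, thin = 5L,
                         seed = NULL) {
  stopifnot(n_samples > 0, burn_in >= 0, thin >= 1)
  L <- model$L; q <- model$q
  Jl <- lapply(seq_len(L), function(i)
    lapply(seq_len(L), function(j) model$J[i, j, , ]))
  with_seed(seed, {
    s <- sample.int(q, L, replace = TRUE)
    out <- matrix(0L, n_samples, L)
    sweep_once <- function(s) {
      for (i in seq_len(L)) {
        e <- model$h[i, ]
        for (j in seq_len(L)) if (j != i) e <- e + Jl[[i]][[j]][, s[j]]
        p <- exp(e - max(e))
        s[i] <- sample.int(q, 1L, prob = p)
      }
      s
    }
    for (t in seq_len(burn_in)) s <- sweep_once(s)
    for (m in seq_len(n_samples)) {
      for (t in seq_len(thin)) s <- sweep_once(s)
      out[m, ] <- s
    }
    out
  })
}

#' Corrupt an aligned sequence into an unaligned query with known truth
#'
#' Gap states are deleted (x_i = 0 there); at each of the L + 1 boundaries,
#' with probability `insert_rate`, a geometric-length run (1 + Geom(p),
#' mean 1/p) of uniform random non-gap residues is inserted. The true
#' pointer vector n is computed by the same counter walk as
#' [pointer_trajectory()], so the returned truth is always feasible.
#'
#' @param aligned integer vector of length L (gap = q).
#' @param insert_rate per-boundary insertion probability in [0, 1).
#' @param insert_len_param geometric success parameter p in (0, 1].
#' @param alphabet the model's alphabet.
#' @param seed RNG seed.
#' @return `list(query, x, n, N)`, or `NULL` (with a warning) for an
#'   all-gap input, which is unalignable.
#' @export
corrupt_to_query <- function(aligned, insert_rate = 0.1, insert_len_param = 2/3,
                             alphabet, seed = NULL) {
  stopifnot(insert_rate >= 0, insert_rate < 1,
            insert_len_param > 0, insert_len_param <= 1)
  gap <- alphabet$gap
  L <- length(aligned)
  if (all(aligned == gap)) {
    warning("all-gap aligned input: empty query is unalignable")
    return(NULL)
  }
  with_seed(seed, {
    query <- integer(0)
    x <- integer(L); n <- integer(L)
    counter <- 0L
    draw_insert <- function() {
      if (stats::runif(1) < insert_rate) {
        len <- stats::rgeom(1L, insert_len_param) + 1L
        sample.int(gap - 1L, len, replace = TRUE)
      } else integer(0)
    }
    prev <- 0L
    for (i in seq_len(L)) {
      ins <- draw_insert()
      query <- c(query, ins); counter <- counter + length(ins)
      if (aligned[i] != gap) {
        query <- c(query, aligned[i]); counter <- counter + 1L
        x[i] <- 1L; prev <- counter
      } else {
        x[i] <- 0L
      }
      n[i] <- prev
    }
    ins <- draw_insert()
    query <- c(query, ins); counter <- counter + length(ins)
    N <- counter
    res <- list(query = query, x = x, n = c(0L, n, N + 1L), N = N)
    stopifnot(is_feasible(res$x, res$n, N))
    res
  })
}

# draw insert runs for the L+1 boundaries of one row: at each boundary,
# with probability insert_rate, a 1 + Geom(p) run of uniform non-gap residues
draw_insert_runs <- function(L, q, insert_rate, insert_len_param) {
  lapply(seq_len(L + 1L), function(b) {
    if (stats::runif(1) < insert_rate) {
      len <- stats::rgeom(1L, insert_len_param) + 1L
      sample.int(q - 1L, len, replace = TRUE)
    } else integer(0)
  })
}

#' Seed MSA from a matrix of aligned sampled sequences
#'
#' @param mat integer matrix (rows x L), gap = q.
#' @param alphabet the matching alphabet.
#' @param ids optional row ids.
#' @return a `seed_msa` with empty insert runs and unit weights.
#' @export
msa_from_matrix <- function(mat, alphabet, ids = NULL) {
  L <- ncol(mat)
  if (is.null(ids)) ids <- sprintf("synthetic_%d", seq_len(nrow(mat)))
  rows <- lapply(seq_len(nrow(mat)), function(m)
    new_seed_row(ids[m], mat[m, ], rep(list(integer(0)), L + 1L)))
  new_seed_msa(alphabet, rows)
}

default_planted_pairs <- function(L) {
  k <- max(1L, L %/% 3L)
  cbind(i = seq_len(k), j = seq_len(k) + L %/% 2L)
}

#' Generate a complete planted family
#'
#' Study conditions (defaults): L = 12 columns, q = 4 states (3 letters +
#' gap), 1000 seed rows, 50 queries, single-site gap rate 0.1, per-boundary
#' insert rate 0.1 with geometric mean length 1.5, coupling strength 1.0 on
#' 4 planted pairs and field strength 2.0 (majority-residue frequencies
#' around 0.7-0.85, the conservation level of curated match columns, which
#' is the regime a seed-based aligner presumes). Seed rows carry insert-state
#' runs drawn with the same insertion statistics as the queries, emulating
#' a real seed alignment's insert columns; without them the pointer priors
#' would declare insertions unseen and the alignment problem would be
#' degenerate. Queries shorter than L (more deleted gaps than inserted
#' residues) are outside the aligner's domain and are redrawn; the number
#' redrawn is logged.
#'
#' @param L,q model size.
#' @param n_seed,n_queries seed rows and queries to generate.
#' @param pairs planted coupled pairs (default [default_planted_pairs()]).
#' @param coupling_strength,field_strength parameter scales.
#' @param gap_rate target per-column gap probability.
#' @param insert_rate,insert_len_param query corruption parameters.
#' @param seed RNG seed for the whole family.
#' @return a `planted_family`: `model`, `seed_msa`, `queries` (list of
#'   `list(id, seq, N)`), `truth` (list of `list(x, n)`), `params`.
#' @export
make_planted_family <- function(L = 12L, q = 4L, n_seed = 1000L,
                                n_queries = 50L, pairs = NULL,
                                coupling_strength = 1, field_strength = 2,
                                gap_rate = 0.1, insert_rate = 0.1,
                                insert_len_param = 2/3, seed = NULL) {
  if (is.null(pairs)) pairs <- default_planted_pairs(L)
  with_seed(seed, {
    model <- make_planted_model(L, q, pairs, coupling_strength,
                                field_strength, gap_rate = gap_rate)
    seed_mat <- gibbs_sample(model, n_seed)
    rows <- lapply(seq_len(n_seed), function(m)
      new_seed_row(sprintf("synthetic_%d", m), seed_mat[m, ],
                   draw_insert_runs(L, q, insert_rate, insert_len_param)))
    msa <- new_seed_msa(model$alphabet, rows)
    queries <- list(); truth <- list()
    redrawn <- 0L
    while (length(queries) < n_queries) {
      al <- gibbs_sample(model, 1L, burn_in = 50L, thin = 1L)[1L, ]
      if (all(al == model$alphabet$gap)) { redrawn <- redrawn + 1L; next }
      cq <- corrupt_to_query(al, insert_rate, insert_len_param, model$alphabet)
      if (cq$N < L) { redrawn <- redrawn + 1L; next }
      k <- length(queries) + 1L
      queries[[k]] <- list(id = sprintf("query_%d", k), seq = cq$query, N = cq$N)
      truth[[k]] <- list(x = cq$x, n = cq$n)
    }
    if (redrawn > 0L)
      pa_log("info", "redrew %d corrupted queries with N < L (unalignable)", redrawn)
    structure(list(model = model, seed_msa = msa, queries = queries,
                   truth = truth,
                   params = list(L = L, q = q, n_seed = n_seed,
                                 n_queries = n_queries, pairs = pairs,
                                 coupling_strength = coupling_strength,
                                 field_strength = field_strength,
                                 gap_rate = gap_rate, insert_rate = insert_rate,
                                 insert_len_param = insert_len_param,
                                 seed = seed)),
              class = "planted_family")
  })
}

#' @export
print.planted_family <- function(x, ...) {
  cat(sprintf("<planted_family> L=%d q=%d seed rows=%d queries=%d planted pairs=%d\n",
              x$params$L, x$params$q, length(x$seed_msa$rows),
              length(x$queries), nrow(x$params$pairs)))
  invisible(x)
}
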