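test_that("feasibility matches its definition and the closed-form count", {
  expect_true(is_feasible(c(1, 1), c(0, 1, 2, 3), 2))
  expect_false(is_feasible(c(1, 1), c(0, 2, 1, 3), 2))   # decreasing pointers
  expect_false(is_feasible(c(0, 1), c(0, 1, 2, 3), 2))   # gap must carry
  expect_true(is_feasible(c(0, 1), c(0, 0, 1, 3), 2))
  expect_false(is_feasible(c(1, 1), c(0, 1, 4, 4), 3))   # matched pointer beyond N
  # brute-force enumeration vs closed form
  for (dims in list(c(2, 2), c(2, 3), c(3, 4), c(4, 5))) {
    L <- dims[1]; N <- dims[2]
    grid <- expand.grid(rep(list(0:1), L))
    cnt <- 0
    ncand <- expand.grid(rep(list(0:(N + 1)), L))
    for (r in seq_len(nrow(grid))) for (s in seq_len(nrow(ncand))) {
      if (is_feasible(as.integer(grid[r, ]),
                      c(0L, as.integer(ncand[s, ]), N + 1L), N)) cnt <- cnt + 1
    }
    expect_equal(cnt, count_feasible(L, N))
  }
})

test_that("log objective is linear in beta and reduces to -H under flat priors", {
  model <- random_potts(3, 4, seed = 5)
  set.seed(6)
  N <- 5
  query <- sample.int(3, N, replace = TRUE)
  sts <- replicate(8, {
    st <- random_feasible_state(3, N); st$query <- query; st
  }, simplify = FALSE)
  for (st in sts) {
    expect_equal(log_objective(model, NULL, st, beta = 0), 0)
    o1 <- log_objective(model, NULL, st, beta = 1)
    expect_equal(log_objective(model, NULL, st, beta = 2), 2 * o1)
    expect_equal(o1, -energy(model, st))
  }
})

test_that("message passing is exact on chain factor graphs", {
  for (L in 4:8) {
    model <- random_potts(L, 4, scale = 0.7, seed = L)
    set.seed(L + 100)
    N <- L + 2
    query <- sample.int(3, N, replace = TRUE)
    graph <- build_align_graph(model, NULL, query, chain_only = TRUE)
    for (beta in c(0.5, 1.5)) {
      mp <- mp_state_init(graph, beta, damping = 0, noise = 1e-4, seed = 1)
      for (s in 1:60) if (mp_sweep(mp) < 1e-13) break
      got <- mp_beliefs(mp, log = FALSE)
      want <- chain_exact_marginals(graph, beta)
      expect_lt(max(abs(got - want)), 1e-8)
      expect_equal(colSums(got), rep(1, L), tolerance = 1e-10)
    }
  }
})

test_that("converged beliefs barely depend on the update order", {
  fam <- make_planted_family(L = 5, q = 4, n_seed = 80, n_queries = 1, seed = 31)
  fit <- fit_seed_model(fam$seed_msa)
  query <- fam$queries[[1]]$seq
  graph <- build_align_graph(fit$potts, fit$prior, query)
  bel <- list()
  for (ord in c("forward", "reverse")) {
    mp <- mp_state_init(graph, 0.8, damping = 0.2, noise = 1e-5, seed = 2)
    for (s in 1:300) if (mp_sweep(mp, order = ord) < 1e-12) break
    bel[[ord]] <- mp_beliefs(mp, log = FALSE)
  }
  expect_lt(max(abs(bel$forward - bel$reverse)), 1e-6)
})

test_that("decode returns the feasible maximizer with the documented tie-break", {
  model <- random_potts(2, 4, scale = 0, seed = 1)  # zero model
  query <- c(1L, 2L)
  graph <- build_align_graph(model, NULL, query)
  D <- graph$D
  # point mass on a feasible state: that state comes back
  logb <- matrix(-50, D, 2)
  s1 <- which(graph$xs == 1 & graph$ns == 2)   # (x=1, n=2) at column 1
  s2 <- which(graph$xs == 0 & graph$ns == 2)   # (x=0, n=2) at column 2
  logb[s1, 1] <- 0; logb[s2, 2] <- 0
  st <- pottsalign:::decode_beliefs(logb, graph)
  expect_identical(st$x, c(1L, 0L))
  expect_identical(st$n, c(0L, 2L, 2L, 3L))
  # point masses on an infeasible combination: feasible max-total-belief wins
  logb <- matrix(-50, D, 2)
  logb[which(graph$xs == 1 & graph$ns == 2), 1] <- 0  # n_1 = 2
  logb[which(graph$xs == 1 & graph$ns == 1), 2] <- 0  # n_2 = 1 (infeasible after 2)
  st <- pottsalign:::decode_beliefs(logb, graph)
  expect_true(is_feasible(st$x, st$n, 2))
  # exactly one of the two point masses can be kept on a feasible path
  idx1 <- which(graph$xs == st$x[1] & graph$ns == st$n[2])
  idx2 <- which(graph$xs == st$x[2] & graph$ns == st$n[3])
  expect_equal(logb[idx1, 1] + logb[idx2, 2], -50)
  # uniform beliefs: tie-break gives the all-match identity alignment
  st <- pottsalign:::decode_beliefs(matrix(0, D, 2), graph)
  expect_identical(st$x, c(1L, 1L))
  expect_identical(st$n, c(0L, 1L, 2L, 3L))
})

test_that("the exhaustive oracle maximizes over feasible states", {
  # zero model, flat prior: tie-break state
  model <- random_potts(2, 4, scale = 0, seed = 1)
  res <- exhaustive_align(model, NULL, c(1L, 2L))
  expect_identical(res$x, c(1L, 1L))
  expect_identical(res$n, c(0L, 1L, 2L, 3L))
  # dominates random feasible states
  fam <- make_planted_family(L = 4, q = 4, n_seed = 60, n_queries = 3, seed = 23)
  fit <- fit_seed_model(fam$seed_msa)
  for (k in 1:3) {
    query <- fam$queries[[k]]$seq
    ex <- exhaustive_align(fit$potts, fit$prior, query)
    set.seed(k)
    for (r in 1:300) {
      st <- random_feasible_state(4, length(query))
      st$query <- query
      expect_lte(log_objective(fit$potts, fit$prior, st), ex$log_objective + 1e-9)
    }
  }
  # state-space cap refusal
  expect_error(exhaustive_align(random_potts(12, 4, seed = 2), NULL,
                                rep(1L, 20), cap = 1e4),
               "cap exceeded")
})

test_that("annealed message passing recovers exact optima on small instances", {
  set.seed(77)
  sched <- anneal_schedule(beta_start = 0.2, beta_max = 6, growth = 1.3,
                           max_sweeps = 60, tol = 1e-6, damping = 0.3)
  hits <- 0
  for (rep in 1:12) {
    L <- sample(2:4, 1); q <- 4
    model <- random_potts(L, q, scale = 0.6, seed = rep)
    N <- L + sample(0:3, 1)
    query <- sample.int(q - 1, N, replace = TRUE)
    ex <- exhaustive_align(model, NULL, query)
    an <- anneal_align(model, NULL, query, sched, seed = rep)
    expect_lte(an$log_objective, ex$log_objective + 1e-9)  # oracle is optimal
    if (abs(an$log_objective - ex$log_objective) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 11)
})

test_that("a query matching a strongly preferred sequence aligns to the identity", {
  ab <- toy_alphabet(4)
  L <- 5
  target <- c(1L, 2L, 3L, 1L, 2L)
  h <- matrix(-2, L, 4)
  h[cbind(seq_len(L), target)] <- 4
  model <- new_potts_model(ab, h, array(0, dim = c(L, L, 4, 4)))
  ex <- exhaustive_align(model, NULL, target)     # identity is the optimum
  expect_identical(ex$n, c(0L, 1L, 2L, 3L, 4L, 5L, 6L))
  an <- anneal_align(model, NULL, target, anneal_schedule(growth = 1.3), seed = 1)
  expect_identical(an$x, rep(1L, L))
  expect_identical(an$n, ex$n)
})

test_that("L = 1 picks the best placement of the single column", {
  ab <- toy_alphabet(4)
  h <- matrix(c(-1, 3, -1, -5), 1, 4)  # prefers the second state (C)
  model <- new_potts_model(ab, h, array(0, dim = c(1, 1, 4, 4)))
  query <- c(1L, 1L, 2L, 1L)           # B at position 3
  an <- anneal_align(model, NULL, query, anneal_schedule(growth = 1.5), seed = 1)
  expect_identical(an$x, 1L)
  expect_identical(an$n, c(0L, 3L, 5L))
})

test_that("alignment is deterministic under a fixed seed and rejects N < L", {
  fam <- make_planted_family(L = 4, q = 4, n_seed = 50, n_queries = 1, seed = 41)
  fit <- fit_seed_model(fam$seed_msa)
  query <- fam$queries[[1]]$seq
  sched <- anneal_schedule(growth = 1.4)
  r1 <- anneal_align(fit$potts, fit$prior, query, sched, seed = 9)
  r2 <- anneal_align(fit$potts, fit$prior, query, sched, seed = 9)
  expect_identical(r1, r2)
  expect_error(anneal_align(fit$potts, fit$prior, c(1L, 2L), sched, seed = 1),
               "N.*smaller than the model|L <= N")
  # decode output is always feasible
  expect_true(is_feasible(r1$x, r1$n, r1$N))
})
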