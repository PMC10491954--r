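test_that("planted models are reproducible, gauged and carry their pairs", {
  m1 <- make_planted_model(6, 4, pairs = rbind(c(1, 4), c(2, 6)), seed = 5)
  m2 <- make_planted_model(6, 4, pairs = rbind(c(1, 4), c(2, 6)), seed = 5)
  expect_identical(m1$h, m2$h)
  expect_identical(m1$J, m2$J)
  expect_identical(m1$gauge, "zero_sum")
  expect_equal(attr(m1, "planted_pairs"), rbind(c(1, 4), c(2, 6)))
  # couplings live only on the planted pairs
  mx <- apply(abs(m1$J), c(1, 2), max)
  expect_true(all(mx[cbind(c(1, 2), c(4, 6))] > 0.1))
  off <- mx; off[cbind(c(1, 2, 4, 6), c(4, 6, 1, 2))] <- 0; diag(off) <- 0
  expect_lt(max(off), 1e-12)
  # zero coupling strength gives an independent-columns model
  m0 <- make_planted_model(6, 4, pairs = rbind(c(1, 4)), coupling_strength = 0, seed = 5)
  expect_true(all(m0$J == 0))
})

test_that("gap-rate calibration puts the requested mass on the gap state", {
  model <- make_planted_model(4, 4, pairs = cbind(1, 3), coupling_strength = 0,
                              field_strength = 2, gap_rate = 0.2, seed = 8)
  # with J = 0 the single-site law is the softmax of the (pre-gauge) fields;
  # gauge shifts preserve it, so check via sampling
  S <- gibbs_sample(model, 4000, burn_in = 50, thin = 1, seed = 9)
  grate <- mean(S == model$alphabet$gap)
  expect_lt(abs(grate - 0.2), 3 * sqrt(0.2 * 0.8 / (4000 * 4)) + 0.02)
})

test_that("Gibbs sampling reproduces single-site laws", {
  ab <- toy_alphabet(4)
  # zero model: uniform one-site frequencies within 3 standard errors
  zero <- new_potts_model(ab, matrix(0, 3, 4), array(0, dim = c(3, 3, 4, 4)))
  S <- gibbs_sample(zero, 10000, burn_in = 20, thin = 1, seed = 2)
  f <- colMeans(S == 1)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(f - 0.25) < 3 * se + 0.01))
  # strong field on (site 1, state A) with J = 0: exact closed form
  h <- matrix(0, 3, 4); h[1, 1] <- 2
  model <- new_potts_model(ab, h, array(0, dim = c(3, 3, 4, 4)))
  S <- gibbs_sample(model, 8000, burn_in = 20, thin = 1, seed = 3)
  pA <- exp(2) / (exp(2) + 3)
  expect_lt(abs(mean(S[, 1] == 1) - pA), 3 * sqrt(pA * (1 - pA) / 8000) + 0.01)
  expect_gt(mean(S[, 1] == 1), 0.5)
  # thinning does not change one-site marginals beyond sampling error
  S10 <- gibbs_sample(model, 2000, burn_in = 20, thin = 10, seed = 4)
  expect_lt(abs(mean(S10[, 1] == 1) - pA), 3 * sqrt(pA * (1 - pA) / 2000) + 0.02)
  # determinism
  expect_identical(gibbs_sample(model, 50, 10, 2, seed = 7),
                   gibbs_sample(model, 50, 10, 2, seed = 7))
})

test_that("planted couplings induce covariation detectable as mutual information", {
  model <- make_planted_model(4, 4, pairs = cbind(1, 3), coupling_strength = 1,
                              field_strength = 0.2, seed = 6)
  S <- gibbs_sample(model, 20000, burn_in = 100, thin = 1, seed = 7)
  p12 <- table(factor(S[, 1], 1:4), factor(S[, 3], 1:4)) / nrow(S)
  p1 <- rowSums(p12); p2 <- colSums(p12)
  mi <- sum(p12 * log(p12 / outer(p1, p2)), na.rm = TRUE)
  expect_gt(mi, 0.05)
  # uncoupled pair as control
  p14 <- table(factor(S[, 1], 1:4), factor(S[, 4], 1:4)) / nrow(S)
  mi0 <- sum(p14 * log(p14 / outer(rowSums(p14), colSums(p14))), na.rm = TRUE)
  expect_lt(mi0, mi / 5)
})

test_that("query corruption returns a feasible truth that replays the walk", {
  ab <- toy_alphabet(4)
  # no gaps, no inserts: the query is the aligned string, identity truth
  aligned <- c(1L, 2L, 3L, 1L)
  cq <- corrupt_to_query(aligned, insert_rate = 0, insert_len_param = 0.5,
                         alphabet = ab, seed = 1)
  expect_identical(cq$query, aligned)
  expect_identical(cq$n, c(0L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(cq$x, rep(1L, 4))
  # all-gap input is rejected with a warning
  expect_warning(out <- corrupt_to_query(rep(4L, 3), 0.1, 0.5, ab, seed = 1),
                 "unalignable")
  expect_null(out)
  # property: feasibility and bookkeeping over many random draws
  set.seed(99)
  for (rep in 1:400) {
    L <- sample(2:8, 1)
    aligned <- sample.int(4, L, replace = TRUE)
    if (all(aligned == 4L)) next
    cq <- corrupt_to_query(aligned, insert_rate = 0.3, insert_len_param = 0.5,
                           alphabet = ab)
    expect_true(is_feasible(cq$x, cq$n, cq$N))
    expect_identical(cq$x, as.integer(aligned != 4L))
    # matched residues appear at their pointers
    for (i in which(cq$x == 1L))
      expect_identical(cq$query[cq$n[i + 1L]], aligned[i])
  }
})

test_that("planted families are coherent and reproducible", {
  fam <- make_planted_family(L = 6, q = 4, n_seed = 40, n_queries = 5, seed = 12)
  fam2 <- make_planted_family(L = 6, q = 4, n_seed = 40, n_queries = 5, seed = 12)
  expect_identical(fam$queries, fam2$queries)
  expect_identical(seed_matrix(fam$seed_msa), seed_matrix(fam2$seed_msa))
  for (k in seq_along(fam$queries)) {
    expect_gte(fam$queries[[k]]$N, 6L)
    expect_true(is_feasible(fam$truth[[k]]$x, fam$truth[[k]]$n, fam$queries[[k]]$N))
  }
  # seed rows carry insert runs with the query statistics (some nonzero)
  ins <- sum(vapply(fam$seed_msa$rows, function(r) sum(lengths(r$insert_runs)), numeric(1)))
  expect_gt(ins, 0)
})
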