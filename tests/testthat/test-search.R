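all_pairs_candidates <- function(d) {
  g <- expand.grid(control = 0:(d - 1), target = 0:(d - 1))
  g <- g[g$control != g$target, ]
  g$max_abs_delta <- 1
  rownames(g) <- NULL
  g
}

test_that("local search returns the empty topology at a perfect baseline", {
  psi1 <- random_amplitudes(1, 1); psi2 <- random_amplitudes(2, 2)
  ini <- tensor_initial_state(psi1, psi2)
  res <- nwise_local_search(all_pairs_candidates(3), ini,
                            as.numeric(psi1)^2, as.numeric(psi2)^2)
  expect_equal(nrow(res$topology), 0)
  expect_equal(res$kl_final, 0, tolerance = 1e-9)
  # empty candidate set is tolerated
  empty <- data.frame(control = integer(0), target = integer(0))
  res2 <- nwise_local_search(empty, ini, c(0.3, 0.7), c(1, 0, 0, 0))
  expect_equal(nrow(res2$topology), 0)
})

test_that("local search recovers a planted single-gate transformation", {
  prob <- planted_problem(2, 2, topology(0, 2, pi / 2), seed = 3)
  res <- nwise_local_search(prob$candidates, prob$initial, prob$q_ct1,
                            prob$q_ct2)
  expect_lt(res$kl_final, 1e-6)
  expect_lte(res$kl_final, res$kl_initial)
})

test_that("accepted local-search moves never increase the trace cost", {
  prob <- planted_problem(2, 3, topology(c(0, 2), c(2, 4), pi / 2), seed = 5)
  res <- nwise_local_search(prob$candidates, prob$initial, prob$q_ct1,
                            prob$q_ct2)
  expect_true(all(diff(res$trace$cost) <= 0))
  expect_lt(res$kl_final, 1e-6)
})

test_that("multi-epoch search is seeded-deterministic and prunes redundancy", {
  prob <- planted_problem(2, 2, topology(1, 3, pi / 2), seed = 9)
  r1 <- multi_epoch_search(prob$candidates, prob$initial, prob$q_ct1,
                           prob$q_ct2, epochs = 5, seed = 42)
  r2 <- multi_epoch_search(prob$candidates, prob$initial, prob$q_ct1,
                           prob$q_ct2, epochs = 5, seed = 42)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$trace, r2$trace)
  expect_lt(r1$kl_final, 1e-6)
  # no remaining gate is removable within the Occam tolerance
  fn <- qccc:::make_cost_fn(prob$candidates, prob$initial, prob$q_ct1,
                            prob$q_ct2, eps = 1e-10)
  for (p in seq_along(r1$sequence)) {
    expect_gt(fn$cost(r1$sequence[-p]), r1$kl_final + 1e-4)
  }
})

test_that("a single beneficial candidate yields a one-gate topology", {
  # concentrated baseline so the planted gate moves real probability mass
  psi1 <- amplitudes_from_counts(state_table(c("0" = 1L, "1" = 9L), "gA"))
  psi2 <- amplitudes_from_counts(state_table(c("0" = 9L, "1" = 1L), "gB"))
  pl <- generate_planted_circuit(topology(0, 1, pi / 2), psi1, psi2,
                                 exact = TRUE)
  one <- data.frame(control = 0L, target = 1L, max_abs_delta = 1)
  res <- multi_epoch_search(one, pl$initial, pl$q_ct1, pl$q_ct2,
                            epochs = 1, seed = 1)
  expect_equal(nrow(res$topology), 1)
  expect_lt(res$kl_final, res$kl_initial)
})

test_that("QUBO selection keeps beneficial gates and drops harmful ones", {
  psi1 <- amplitudes_from_counts(state_table(c("10" = 7L, "01" = 3L),
                                             c("gA", "gB")))
  psi2 <- amplitudes_from_counts(state_table(c("00" = 8L, "11" = 2L),
                                             c("gC", "gD")))
  pl <- generate_planted_circuit(topology(0, 2, pi / 2), psi1, psi2,
                                 exact = TRUE)
  # row 1 realizes the planted transformation; the others only disturb it
  cand <- data.frame(control = c(0L, 1L, 3L, 2L, 1L, 3L),
                     target = c(2L, 3L, 0L, 1L, 0L, 2L),
                     max_abs_delta = seq(1, 0.5, length.out = 6))
  res <- qubo_select_and_order(cand, pl$initial, pl$q_ct1, pl$q_ct2,
                               backend = "exact")
  expect_lte(res$kl_final, res$kl_initial + 1e-9)
  expect_lt(res$kl_final, 1e-6)
  expect_true(1L %in% res$sequence)
  # exact enumeration and annealing agree on the selected set
  ra <- qubo_select_and_order(cand, pl$initial, pl$q_ct1, pl$q_ct2,
                              backend = "anneal", seed = 7)
  expect_identical(sort(unique(res$sequence)), sort(unique(ra$sequence)))
})

test_that("QUBO ordering stage evaluates permutations with canonical ties", {
  # two commuting gates: both orders tie, the candidate-rank order is kept
  psi1 <- random_amplitudes(2, 11); psi2 <- random_amplitudes(2, 12)
  ini <- tensor_initial_state(psi1, psi2)
  tau <- topology(c(0, 2), c(1, 3), pi / 2)
  pl <- generate_planted_circuit(tau, psi1, psi2, exact = TRUE)
  cand <- data.frame(control = c(0, 2), target = c(1, 3),
                     max_abs_delta = c(1, 0.5))
  res <- qubo_select_and_order(cand, ini, pl$q_ct1, pl$q_ct2,
                               backend = "exact")
  expect_equal(res$sequence, c(1L, 2L))
  expect_lt(res$kl_final, 1e-9)
})

test_that("every algorithm ends at or below the baseline cost", {
  prob <- planted_problem(2, 2, topology(c(0, 1), c(2, 3), pi / 2), seed = 13)
  for (alg in c("nwise", "multi_epoch", "qubo")) {
    res <- search_topology(prob$candidates, prob$initial, prob$q_ct1,
                           prob$q_ct2, algorithm = alg)
    expect_lte(res$kl_final, res$kl_initial + 1e-6)
  }
})
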