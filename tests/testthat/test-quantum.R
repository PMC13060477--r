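basis_state <- function(bits, n1, n2) {
  d <- n1 + n2
  amp <- complex(2^d)
  amp[bits_to_index(bits) + 1] <- 1
  qccc_state(amp, n1, n2)
}

test_that("controlled-RX acts only when the control is set", {
  s00 <- basis_state("00", 1, 1)
  expect_equal(unclass(apply_crx(s00, 0, 1, pi / 2)), unclass(s00),
               ignore_attr = TRUE)
  s10 <- basis_state("10", 1, 1)
  expect_equal(unclass(apply_crx(s10, 0, 1, 0)), unclass(s10),
               ignore_attr = TRUE)
  # RX(pi)|1> = -i|0>: |11> -> -i|10>
  s11 <- basis_state("11", 1, 1)
  out <- unclass(apply_crx(s11, 0, 1, pi))
  expect_equal(out, as.complex(c(0, 0, -1i, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # hand-multiplied RX(pi/2) column: |10> -> (|10> - i|11>)/sqrt(2)
  out2 <- unclass(apply_crx(s10, 0, 1, pi / 2))
  expect_equal(out2, as.complex(c(0, 0, 1 / sqrt(2), -1i / sqrt(2))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Mod(out2)^2, c(0, 0, 0.5, 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(apply_crx(s10, 1, 1, pi), "differ")
  expect_error(apply_crx(s10, 0, 5, pi), "out of range")
})

test_that("simulate matches the dense-matrix oracle on small systems", {
  for (seed in 1:8) {
    set.seed(seed)
    n1 <- sample(1:2, 1); n2 <- sample(1:2, 1)
    d <- n1 + n2
    psi <- tensor_initial_state(random_amplitudes(n1, seed),
                                random_amplitudes(n2, seed + 100))
    tau <- random_topology(d, n_gates = sample(1:5, 1), seed = seed + 200)
    fast <- unclass(simulate_circuit(tau, psi))
    dense <- simulate_dense(tau, unclass(psi), d)
    expect_equal(fast, dense, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("empty topologies and commuting gates behave as expected", {
  psi <- tensor_initial_state(random_amplitudes(2, 1), random_amplitudes(2, 2))
  expect_equal(unclass(simulate_circuit(topology(), psi)),
               unclass(psi), ignore_attr = TRUE)
  # gates on disjoint qubit pairs commute
  t_ab <- topology(c(0, 2), c(1, 3), c(0.7, 1.9))
  t_ba <- topology(c(2, 0), c(3, 1), c(1.9, 0.7))
  expect_equal(unclass(simulate_circuit(t_ab, psi)),
               unclass(simulate_circuit(t_ba, psi)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("simulation is unitary for random topologies", {
  for (seed in 1:10) {
    psi <- tensor_initial_state(random_amplitudes(2, seed),
                                random_amplitudes(2, seed + 10))
    tau <- random_topology(4, 6, seed)
    out <- simulate_circuit(tau, psi)
    expect_equal(sqrt(sum(Mod(unclass(out))^2)), 1, tolerance = 1e-10)
  }
})

test_that("marginals recover register distributions", {
  psi1 <- random_amplitudes(2, 3); psi2 <- random_amplitudes(2, 4)
  s <- tensor_initial_state(psi1, psi2)
  expect_equal(as.numeric(marginal(s, "CT1")), as.numeric(psi1)^2,
               tolerance = 1e-12)
  expect_equal(as.numeric(marginal(s, "CT2")), as.numeric(psi2)^2,
               tolerance = 1e-12)
  # Bell-like state: both single-qubit marginals are uniform
  bell <- qccc_state(c(1, 0, 0, 1) / sqrt(2), 1, 1)
  expect_equal(as.numeric(marginal(bell, "CT1")), c(0.5, 0.5))
  expect_equal(as.numeric(marginal(bell, "CT2")), c(0.5, 0.5))
  for (seed in 1:5) {
    s <- simulate_circuit(random_topology(4, 4, seed),
                          tensor_initial_state(random_amplitudes(2, seed),
                                               random_amplitudes(2, seed + 5)))
    expect_equal(sum(marginal(s, "CT1")), 1, tolerance = 1e-12)
    expect_equal(sum(marginal(s, "CT2")), 1, tolerance = 1e-12)
  }
})

test_that("KL divergence is smoothed, non-negative, and zero iff equal", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-12)
  # closed form log 2 as smoothing vanishes
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5), eps = 1e-15), log(2),
               tolerance = 1e-10)
  # smoothing keeps zero-support targets finite, about (1/2) log(1 / 2e-10)
  v <- kl_divergence(c(0.5, 0.5), c(1, 0), eps = 1e-10)
  expect_true(is.finite(v) && v > 0)
  # hand evaluation of the smoothed sum: both P entries are ~1/2, the
  # smoothed Q entries are ~1 and ~1e-10
  expect_equal(v, 0.5 * log(0.5 / 1) + 0.5 * log(0.5 / 1e-10),
               tolerance = 0.01)
  expect_gt(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)), 0)
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "support")
})

test_that("circuit cost sums the two marginal divergences", {
  psi1 <- random_amplitudes(1, 7); psi2 <- random_amplitudes(2, 8)
  ini <- tensor_initial_state(psi1, psi2)
  # perfect baseline: targets equal the baseline marginals
  cost0 <- circuit_cost(topology(), ini,
                        as.numeric(psi1)^2, as.numeric(psi2)^2)
  expect_equal(cost0$total, 0, tolerance = 1e-9)
  q1 <- c(0.2, 0.8); q2 <- c(0.1, 0.2, 0.3, 0.4)
  cost1 <- circuit_cost(topology(), ini, q1, q2)
  expect_equal(cost1$total, cost1$kl_ct1 + cost1$kl_ct2)
  expect_equal(cost1$kl_ct1, kl_divergence(as.numeric(psi1)^2, q1))
  expect_gte(cost1$total, 0)
  # appending zero-angle gates never changes the cost
  tau0 <- topology(c(0, 1), c(2, 0), angle = 0)
  expect_equal(circuit_cost(tau0, ini, q1, q2)$total, cost1$total,
               tolerance = 1e-12)
  expect_error(circuit_cost(topology(), ini, q1, c(0.5, 0.5)),
               "register widths")
})
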