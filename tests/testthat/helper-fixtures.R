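# Shared fixture builders: small state tables, random baseline amplitudes,
# random topologies, and planted-circuit problems.

tbl <- function(...) {
  counts <- c(...)
  d <- nchar(names(counts)[1])
  state_table(counts, gene_order = paste0("g", seq_len(d)))
}

# Random strictly-positive baseline amplitudes for a d-qubit register,
# drawn as seeded integer counts over all states.
random_amplitudes <- function(d, seed, prefix = "q") {
  set.seed(seed)
  counts <- sample.int(20, 2^d, replace = TRUE)
  names(counts) <- index_to_bits(seq_len(2^d) - 1, d)
  amplitudes_from_counts(state_table(counts, paste0(prefix, seq_len(d))))
}

random_topology <- function(d, n_gates, seed, angles = NULL) {
  set.seed(seed)
  ctrl <- integer(n_gates); tgt <- integer(n_gates)
  for (i in seq_len(n_gates)) {
    pair <- sample.int(d, 2)
    ctrl[i] <- pair[1] - 1L; tgt[i] <- pair[2] - 1L
  }
  if (is.null(angles)) angles <- runif(n_gates, 0, 2 * pi)
  topology(ctrl, tgt, angles)
}

# A planted problem: baseline, exact targets reachable by `tau`, and the
# candidate set decoded from the density difference against the true
# interacting joint state (the circuit output itself, which a planted
# benchmark knows exactly).
planted_problem <- function(n1, n2, tau, seed = 1) {
  psi1 <- random_amplitudes(n1, seed, prefix = "a")
  psi2 <- random_amplitudes(n2, seed + 1000, prefix = "b")
  pl <- generate_planted_circuit(tau, psi1, psi2, exact = TRUE)
  psi_co <- simulate_circuit(tau, pl$initial)
  cand <- suppressWarnings(gate_candidates(density_delta(pl$initial, psi_co),
                                           cutoff = 0.01))
  list(initial = pl$initial, q_ct1 = pl$q_ct1, q_ct2 = pl$q_ct2,
       candidates = cand, tau = tau)
}
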