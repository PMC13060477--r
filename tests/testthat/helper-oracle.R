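# Independent dense-matrix oracle for the statevector simulator, and an
# exhaustive enumeration oracle for the topology search. Both are built from
# first principles (explicit Kronecker products, full enumeration) and never
# call the package's sparse kernels.

rx_matrix <- function(theta) {
  matrix(c(cos(theta / 2), -1i * sin(theta / 2),
           -1i * sin(theta / 2), cos(theta / 2)), 2, 2)
}

# Full 2^d x 2^d CRX unitary: P0 at the control with identities elsewhere,
# plus P1 at the control and RX at the target. Qubit 0 is the most
# significant factor of the Kronecker product.
crx_dense <- function(d, control, target, theta) {
  p0 <- diag(c(1, 0)); p1 <- diag(c(0, 1)); id <- diag(2)
  kron_chain <- function(mats) Reduce(kronecker, mats)
  mats_a <- mats_b <- rep(list(id), d)
  mats_a[[control + 1]] <- p0
  mats_b[[control + 1]] <- p1
  mats_b[[target + 1]] <- rx_matrix(theta)
  kron_chain(mats_a) + kron_chain(mats_b)
}

simulate_dense <- function(tau, amp, d) {
  v <- as.complex(amp)
  for (i in seq_len(nrow(tau))) {
    v <- crx_dense(d, tau$control[i], tau$target[i], tau$angle[i]) %*% v
  }
  as.vector(v)
}

# Minimum cost over all ordered subsets (no repetition) of candidate gates
# up to max_size, at fixed pi/2 angles.
exhaustive_min_cost <- function(candidates, initial, q_ct1, q_ct2,
                                max_size = 3) {
  nc <- nrow(candidates)
  best <- circuit_cost(topology(), initial, q_ct1, q_ct2)$total
  seqs <- list(integer(0))
  for (size in seq_len(max_size)) {
    new_seqs <- list()
    for (s in seqs) {
      if (length(s) != size - 1) next
      for (c in setdiff(seq_len(nc), s)) {
        new_seqs[[length(new_seqs) + 1]] <- c(s, c)
      }
    }
    for (s in new_seqs) {
      tau <- topology(candidates$control[s], candidates$target[s], pi / 2)
      best <- min(best, circuit_cost(tau, initial, q_ct1, q_ct2)$total)
    }
    seqs <- c(seqs, new_seqs)
  }
  best
}
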