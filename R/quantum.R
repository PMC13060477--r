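# Statevector simulation of controlled-RX circuits on a two-register system,
# register marginals, and the marginal-KL training cost.
#
# Probabilities are read exactly from amplitudes (infinite-shot limit); a
# seeded sampling mode lives in the synthetic-data generator.

#' Construct a statevector over a two-register system
#'
#' @param amplitudes complex (or numeric) vector of length `2^(n_ct1+n_ct2)`,
#'   basis-ordered under the big-endian convention with the CT1 register in
#'   the most significant qubits.
#' @param n_ct1,n_ct2 register widths (qubits) for the two cell types.
#' @param gene_order optional character vector naming the gene on each qubit.
#' @return object of class `qccc_state`.
#' @export
qccc_state <- function(amplitudes, n_ct1, n_ct2, gene_order = NULL) {
  d <- n_ct1 + n_ct2
  if (length(amplitudes) != 2^d) {
    stop("amplitude vector length must be 2^(n_ct1+n_ct2)")
  }
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (abs(nrm - 1) > 1e-10) {
    stop("statevector must be normalized (L2 norm deviates by ",
         format(abs(nrm - 1)), ")")
  }
  structure(as.complex(amplitudes), n_ct1 = as.integer(n_ct1),
            n_ct2 = as.integer(n_ct2), gene_order = gene_order,
            class = "qccc_state")
}

#' @export
print.qccc_state <- function(x, ...) {
  d <- attr(x, "n_ct1") + attr(x, "n_ct2")
  cat("Statevector on", attr(x, "n_ct1"), "+", attr(x, "n_ct2"),
      "qubits (", 2^d, "basis states )\n")
  p <- Mod(x)^2
  top <- order(p, decreasing = TRUE)[seq_len(min(5, length(p)))]
  for (i in top) {
    if (p[i] < 1e-12) next
    cat(sprintf("  |%s>  p = %.4f\n", index_to_bits(i - 1, d), p[i]))
  }
  invisible(x)
}

#' Define an entangling-circuit topology
#'
#' A topology is an ordered sequence of controlled-RX gates; order is
#' significant (gates need not commute) and duplicates are allowed.
#'
#' @param control,target integer vectors of 0-based qubit indices (recycled
#'   to common length); elementwise `control != target`.
#' @param angle rotation angles in radians, recycled; default `pi/2`, the
#'   fixed angle used during the discrete topology search.
#' @return data.frame with columns `control`, `target`, `angle` and class
#'   `qccc_topology`.
#' @examples
#' topology(control = c(0, 2), target = c(2, 1), angle = pi / 2)
#' @export
topology <- function(control = integer(0), target = integer(0),
                     angle = pi / 2) {
  n <- max(length(control), length(target))
  if (n == 0) {
    df <- data.frame(control = integer(0), target = integer(0),
                     angle = numeric(0))
    class(df) <- c("qccc_topology", "data.frame")
    return(df)
  }
  df <- data.frame(control = as.integer(rep_len(control, n)),
                   target = as.integer(rep_len(target, n)),
                   angle = as.numeric(rep_len(angle, n)))
  if (any(df$control == df$target)) stop("control and target must differ")
  if (any(df$control < 0) || any(df$target < 0)) {
    stop("qubit indices must be non-negative")
  }
  class(df) <- c("qccc_topology", "data.frame")
  df
}

#' @export
print.qccc_topology <- function(x, ...) {
  cat("CRX topology with", nrow(x), "gate(s)\n")
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}

#' Apply one controlled-RX gate to a statevector
#'
#' CRX applies the single-qubit rotation
#' `RX(theta) = [[cos(theta/2), -i sin(theta/2)], [-i sin(theta/2),
#' cos(theta/2)]]` to the target qubit on the subspace where the control
#' qubit is 1.
#'
#' @param state a `qccc_state`.
#' @param control,target 0-based qubit indices, distinct.
#' @param angle rotation angle in radians.
#' @return the transformed `qccc_state` (norm preserved).
#' @export
apply_crx <- function(state, control, target, angle) {
  stopifnot(inherits(state, "qccc_state"))
  d <- attr(state, "n_ct1") + attr(state, "n_ct2")
  control <- as.integer(control); target <- as.integer(target)
  if (control == target) stop("control and target must differ")
  if (control < 0 || control >= d || target < 0 || target >= d) {
    stop("qubit index out of range [0, ", d, ")")
  }
  amp <- unclass(state)
  amp <- crx_kernel(amp, d, control, target, angle)
  attributes(amp) <- attributes(state)
  amp
}

# In-place CRX on a bare complex vector of length 2^d.
crx_kernel <- function(amp, d, control, target, angle) {
  mask_c <- bitwShiftL(1L, d - 1L - control)
  mask_t <- bitwShiftL(1L, d - 1L - target)
  idx <- 0:(2^d - 1L)
  i0 <- idx[bitwAnd(idx, mask_c) > 0L & bitwAnd(idx, mask_t) == 0L] + 1L
  i1 <- i0 + mask_t
  a0 <- amp[i0]; a1 <- amp[i1]
  c <- cos(angle / 2); s <- sin(angle / 2)
  amp[i0] <- c * a0 - 1i * s * a1
  amp[i1] <- -1i * s * a0 + c * a1
  amp
}

#' Run a circuit topology on an initial statevector
#'
#' Applies the gates of `tau` in sequence order.
#'
#' @param tau a `qccc_topology`.
#' @param initial a `qccc_state`.
#' @return the output `qccc_state` `psi' = U(tau, theta) psi`.
#' @export
simulate_circuit <- function(tau, initial) {
  stopifnot(inherits(tau, "qccc_topology"), inherits(initial, "qccc_state"))
  d <- attr(initial, "n_ct1") + attr(initial, "n_ct2")
  if (nrow(tau) > 0 && (max(tau$control) >= d || max(tau$target) >= d)) {
    stop("topology addresses qubits outside the register")
  }
  amp <- unclass(initial)
  for (g in seq_len(nrow(tau))) {
    amp <- crx_kernel(amp, d, tau$control[g], tau$target[g], tau$angle[g])
  }
  attributes(amp) <- attributes(initial)
  amp
}

#' Marginal probability distribution of one register
#'
#' Born probabilities `|amplitude|^2` summed over the other register.
#'
#' @param state a `qccc_state`.
#' @param register `"CT1"` or `"CT2"`.
#' @return numeric probability vector of length `2^N` (CT1) or `2^M` (CT2),
#'   class `qccc_probdist`.
#' @export
marginal <- function(state, register = c("CT1", "CT2")) {
  stopifnot(inherits(state, "qccc_state"))
  register <- match.arg(register)
  n1 <- attr(state, "n_ct1"); n2 <- attr(state, "n_ct2")
  p <- Mod(unclass(state))^2
  # index = s_CT1 * 2^M + s_CT2: in a (2^M x 2^N) column-major matrix the
  # CT2 state runs over rows and the CT1 state over columns.
  m <- matrix(p, nrow = 2^n2, ncol = 2^n1)
  go <- attr(state, "gene_order")
  if (register == "CT1") {
    structure(colSums(m), gene_order = if (!is.null(go)) go[seq_len(n1)],
              class = "qccc_probdist")
  } else {
    structure(rowSums(m), gene_order = if (!is.null(go)) go[n1 + seq_len(n2)],
              class = "qccc_probdist")
  }
}

#' Smoothed Kullback-Leibler divergence
#'
#' `D(P || Q) = sum P log(P / Q)` after additive smoothing: both arguments
#' receive `eps` on every state and are renormalized. Smoothing keeps the
#' divergence finite when the circuit populates states with zero empirical
#' target probability.
#'
#' @param p,q probability vectors over the same support.
#' @param eps additive smoothing constant (default `1e-10`).
#' @return non-negative scalar; zero iff the smoothed distributions coincide.
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) {
    stop("distributions have different support sizes (", length(p), " vs ",
         length(q), ")")
  }
  pt <- (p + eps) / sum(p + eps)
  qt <- (q + eps) / sum(q + eps)
  # mathematically >= 0 after renormalization; clamp float round-off
  max(0, sum(pt * (log(pt) - log(qt))))
}

#' Marginal-KL training cost of a topology
#'
#' Simulates `psi' = U(tau, theta) psi` and returns
#' `D_KL(P_psi'(CT1) || Q_co(CT1)) + D_KL(P_psi'(CT2) || Q_co(CT2))`:
#' the two register marginals are matched independently, and cross-register
#' correlation is carried implicitly by the entangling topology.
#'
#' @param tau a `qccc_topology`.
#' @param initial baseline `qccc_state`.
#' @param q_ct1,q_ct2 target probability vectors for the two registers.
#' @param eps KL smoothing constant.
#' @return list with components `total`, `kl_ct1`, `kl_ct2`
#'   (`total = kl_ct1 + kl_ct2`), class `qccc_cost`.
#' @export
circuit_cost <- function(tau, initial, q_ct1, q_ct2, eps = 1e-10) {
  if (length(q_ct1) != 2^attr(initial, "n_ct1") ||
      length(q_ct2) != 2^attr(initial, "n_ct2")) {
    stop("target distribution sizes do not match register widths")
  }
  psi <- simulate_circuit(tau, initial)
  k1 <- kl_divergence(marginal(psi, "CT1"), q_ct1, eps = eps)
  k2 <- kl_divergence(marginal(psi, "CT2"), q_ct2, eps = eps)
  structure(list(total = k1 + k2, kl_ct1 = k1, kl_ct2 = k2),
            class = "qccc_cost")
}

#' @export
print.qccc_cost <- function(x, ...) {
  cat(sprintf("Marginal KL cost: total %.6g (CT1 %.6g + CT2 %.6g)\n",
              x$total, x$kl_ct1, x$kl_ct2))
  invisible(x)
}
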