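# Candidate-gate pruning: threshold the difference of the global density
# matrices of the interacting and non-interacting systems, and decode the
# surviving off-diagonal elements into (control, target) gate proposals.

#' Difference of global density matrices
#'
#' `delta_rho = |psi_co><psi_co| - |psi_mo><psi_mo|`. With real amplitude
#' encodings (counts are always real) both outer products are real
#' symmetric; for complex statevectors the Hermitian difference is kept and
#' downstream thresholding uses element magnitudes. The trace of the
#' difference is always zero.
#'
#' @param psi_mo,psi_co statevectors (`qccc_state`) of equal dimension for
#'   the non-interacting and interacting systems.
#' @return matrix `2^d x 2^d` (real when both inputs are real) of class
#'   `qccc_density_delta`, with the register widths carried as attributes.
#' @export
density_delta <- function(psi_mo, psi_co) {
  stopifnot(inherits(psi_mo, "qccc_state"), inherits(psi_co, "qccc_state"))
  if (length(psi_mo) != length(psi_co)) {
    stop("statevectors have different dimensions")
  }
  a_mo <- unclass(psi_mo); a_co <- unclass(psi_co)
  delta <- outer(a_co, Conj(a_co)) - outer(a_mo, Conj(a_mo))
  if (all(Im(delta) == 0)) delta <- Re(delta)
  structure(delta, n_ct1 = attr(psi_mo, "n_ct1"),
            n_ct2 = attr(psi_mo, "n_ct2"),
            gene_order = attr(psi_mo, "gene_order"),
            class = c("qccc_density_delta", "matrix"))
}

#' Decode a thresholded density difference into candidate gates
#'
#' For every off-diagonal element `(i, j)` with `|delta_rho[i, j]| > cutoff`,
#' the basis bitstrings `s_i` and `s_j` are compared: each bit position where
#' they differ is a candidate target qubit, and each position where both are
#' 1 is a candidate control. All resulting ordered (control, target) pairs
#' are emitted, deduplicated, and ranked by the largest `|delta_rho|` element
#' that proposed them. The rationale: a CRX gate moves amplitude exactly
#' between basis pairs that differ on the target bit while the control bit
#' is set. Pairs within one register (intracellular) and across registers
#' (intercellular) are both kept.
#'
#' @param delta a `qccc_density_delta`.
#' @param cutoff threshold on `|delta_rho|` elements (default 0.01).
#' @return data.frame of class `qccc_candidates` with columns `control`,
#'   `target`, `max_abs_delta`, sorted by decreasing `max_abs_delta` (ties:
#'   control then target); zero rows (with a warning) if nothing survives
#'   the cutoff. Raising the cutoff never adds candidates.
#' @export
gate_candidates <- function(delta, cutoff = 0.01) {
  stopifnot(inherits(delta, "qccc_density_delta"), cutoff > 0)
  d <- attr(delta, "n_ct1") + attr(delta, "n_ct2")
  m <- Mod(unclass(delta))
  hits <- which(m > cutoff, arr.ind = TRUE)
  hits <- hits[hits[, 1] != hits[, 2], , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1] - 1L; j <- hits[r, 2] - 1L
    bi <- qubit_bit(i, 0:(d - 1L), d)
    bj <- qubit_bit(j, 0:(d - 1L), d)
    targets <- which(bi != bj) - 1L
    controls <- which(bi == 1L & bj == 1L) - 1L
    if (length(targets) == 0 || length(controls) == 0) next
    pairs <- expand.grid(control = controls, target = targets)
    pairs <- pairs[pairs$control != pairs$target, , drop = FALSE]
    if (nrow(pairs) == 0) next
    pairs$max_abs_delta <- m[hits[r, 1], hits[r, 2]]
    out[[length(out) + 1L]] <- pairs
  }
  if (length(out) == 0) {
    warning("no density-difference element exceeds the cutoff; ",
            "candidate set is empty")
    res <- data.frame(control = integer(0), target = integer(0),
                      max_abs_delta = numeric(0))
  } else {
    all <- do.call(rbind, out)
    agg <- stats::aggregate(max_abs_delta ~ control + target, data = all,
                            FUN = max)
    res <- agg[order(-agg$max_abs_delta, agg$control, agg$target), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, n_ct1 = attr(delta, "n_ct1"), n_ct2 = attr(delta, "n_ct2"),
            gene_order = attr(delta, "gene_order"),
            class = c("qccc_candidates", "data.frame"))
}

#' Export a candidate set as TSV
#'
#' Columns: control_qubit, target_qubit, control_gene, target_gene,
#' max_abs_delta.
#'
#' @param candidates a `qccc_candidates`.
#' @param path output file path.
#' @param gene_map optional character vector mapping qubit index + 1 to a
#'   gene name; defaults to the `gene_order` attribute.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path, gene_map = NULL) {
  gene_map <- gene_map %||% attr(candidates, "gene_order")
  df <- data.frame(
    control_qubit = candidates$control,
    target_qubit = candidates$target,
    control_gene = if (!is.null(gene_map)) gene_map[candidates$control + 1L]
                   else NA_character_,
    target_gene = if (!is.null(gene_map)) gene_map[candidates$target + 1L]
                  else NA_character_,
    max_abs_delta = candidates$max_abs_delta
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
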