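# Encoding: raw counts -> normalized expression -> binary state tables ->
# amplitude vectors and target probability distributions.

#' Total-count normalization and log1p transform
#'
#' Scales every cell (row) to a common total count, then applies
#' `log(1 + x)` elementwise. The default scaling target is the median cell
#' total, so a typical cell is left roughly unchanged.
#'
#' @param counts numeric matrix, cells x genes, non-negative raw counts.
#'   Column names are gene identifiers; row names (if any) are cell
#'   identifiers.
#' @param target_total scale each cell to this total count. Default `NULL`
#'   uses the median of the per-cell totals.
#' @return numeric matrix of the same shape with log-normalized expression.
#' @details Cells whose total count is zero cannot be scaled and are rejected
#'   with an error naming the offending cells; filter them out (or keep
#'   non-selected background genes in the matrix) before calling.
#' @examples
#' m <- rbind(c1 = c(gA = 2, gB = 2), c2 = c(gA = 8, gB = 2))
#' normalize_log1p(m)
#' @export
normalize_log1p <- function(counts, target_total = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("raw counts must be finite and non-negative")
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("all-zero cell(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (sum(totals == 0) > 5) " ..." else "")
  }
  if (is.null(target_total)) target_total <- stats::median(totals)
  log1p(counts * (target_total / totals))
}

#' Binarize expression and tabulate cellular states
#'
#' Each selected gene is called active (bit 1) when its expression exceeds
#' `threshold`; every cell then becomes a bitstring over `genes` in order,
#' and identical states are aggregated into counts.
#'
#' @param x numeric matrix, cells x genes, typically output of
#'   [normalize_log1p()].
#' @param genes character vector of gene identifiers defining the register
#'   (bit order). Default: all columns of `x` in matrix order.
#' @param threshold activity threshold; bit is 1 iff expression is strictly
#'   greater. Default 0, i.e. any non-zero log-normalized expression.
#' @return a `qccc_state_table`: list with `gene_order`, `counts` (named
#'   integer vector, names are bitstrings), and `n_cells`.
#' @examples
#' x <- rbind(c(1, 0), c(1, 0), c(0, 1))
#' colnames(x) <- c("gA", "gB")
#' binarize(x)
#' @export
binarize <- function(x, genes = colnames(x), threshold = 0) {
  x <- as.matrix(x)
  if (is.null(genes) || length(genes) == 0) {
    stop("empty gene selection: `genes` must name at least one column")
  }
  missing <- setdiff(genes, colnames(x))
  if (length(missing) > 0) {
    stop("genes not present in matrix: ", paste(missing, collapse = ", "))
  }
  bits <- (x[, genes, drop = FALSE] > threshold) + 0L
  states <- apply(bits, 1L, paste, collapse = "")
  tab <- table(states)
  state_table(stats::setNames(as.integer(tab), names(tab)), gene_order = genes)
}

#' Construct a binary state table
#'
#' @param counts named positive integer vector; names are bitstrings of equal
#'   width `d`.
#' @param gene_order character vector of length `d` naming the gene on each
#'   bit position (leftmost first).
#' @return object of class `qccc_state_table`.
#' @export
state_table <- function(counts, gene_order) {
  if (length(counts) == 0) stop("state table must contain at least one state")
  if (is.null(names(counts)) || any(!grepl("^[01]+$", names(counts)))) {
    stop("counts must be named by bitstrings")
  }
  d <- unique(nchar(names(counts)))
  if (length(d) != 1) stop("all bitstrings must have equal width")
  if (length(gene_order) != d) {
    stop("gene_order length (", length(gene_order),
         ") must equal bitstring width (", d, ")")
  }
  if (anyDuplicated(gene_order)) stop("gene_order must be unique")
  counts <- as.integer(counts) |> stats::setNames(names(counts))
  if (any(counts <= 0)) stop("state counts must be strictly positive")
  if (anyDuplicated(names(counts))) stop("duplicate state bitstrings")
  structure(
    list(gene_order = as.character(gene_order),
         counts = counts[order(names(counts))],
         n_cells = sum(counts)),
    class = "qccc_state_table"
  )
}

#' @export
print.qccc_state_table <- function(x, ...) {
  cat("Binary state table:", length(x$gene_order), "genes,",
      x$n_cells, "cells,", length(x$counts), "distinct states\n")
  cat("Gene order:", paste(x$gene_order, collapse = ", "), "\n")
  print(utils::head(x$counts, 10))
  if (length(x$counts) > 10) cat("...\n")
  invisible(x)
}

#' Baseline amplitudes from state counts
#'
#' L2-normalizes the per-state counts of the non-interacting population:
#' `a_s = C(s) / sqrt(sum_s' C(s')^2)`. States never observed get amplitude
#' zero.
#'
#' @param table a `qccc_state_table`.
#' @return numeric vector of length `2^d` of non-negative amplitudes with
#'   unit L2 norm, with attribute `gene_order`; class `qccc_amplitudes`.
#' @examples
#' tab <- state_table(c("00" = 3L, "11" = 4L), c("gA", "gB"))
#' amplitudes_from_counts(tab)  # (3/5, 0, 0, 4/5)
#' @export
amplitudes_from_counts <- function(table) {
  stopifnot(inherits(table, "qccc_state_table"))
  d <- length(table$gene_order)
  amp <- numeric(2^d)
  amp[bits_to_index(names(table$counts)) + 1L] <- table$counts
  amp <- amp / sqrt(sum(amp^2))
  structure(amp, gene_order = table$gene_order, class = "qccc_amplitudes")
}

#' Target probability distribution from state counts
#'
#' Squares the L2-normalized count amplitudes of the interacting population,
#' `Q(s) = (C(s) / sqrt(sum C^2))^2`, then renormalizes so the probabilities
#' sum to exactly 1 (a safeguard: squaring an exactly L2-normalized vector
#' already sums to 1 up to round-off).
#'
#' Note the squared-L2 convention is not the relative frequency `C(s)/n`:
#' the two agree only when all observed counts are equal.
#'
#' @param table a `qccc_state_table`.
#' @return numeric probability vector of length `2^d` with attribute
#'   `gene_order`; class `qccc_probdist`.
#' @examples
#' tab <- state_table(c("00" = 1L, "01" = 2L, "10" = 2L), c("gA", "gB"))
#' target_distribution(tab)  # (1/9, 4/9, 4/9, 0)
#' @export
target_distribution <- function(table) {
  amp <- amplitudes_from_counts(table)
  q <- as.numeric(amp)^2
  q <- q / sum(q)
  structure(q, gene_order = attr(amp, "gene_order"), class = "qccc_probdist")
}

#' Tensor product of two baseline registers
#'
#' Forms the global initial state of the combined system as the Kronecker
#' product of the two per-cell-type baseline amplitude vectors, CT1 register
#' first (most significant qubits).
#'
#' @param psi1,psi2 amplitude vectors (CT1 and CT2), e.g. from
#'   [amplitudes_from_counts()].
#' @return complex statevector of length `2^(N+M)` with attributes `n_ct1`,
#'   `n_ct2` and `gene_order` (CT1 genes then CT2 genes); class `qccc_state`.
#' @export
tensor_initial_state <- function(psi1, psi2) {
  n1 <- round(log2(length(psi1)))
  n2 <- round(log2(length(psi2)))
  stopifnot(2^n1 == length(psi1), 2^n2 == length(psi2))
  v <- kronecker(as.complex(psi1), as.complex(psi2))
  g1 <- attr(psi1, "gene_order") %||% paste0("ct1_q", seq_len(n1) - 1)
  g2 <- attr(psi2, "gene_order") %||% paste0("ct2_q", seq_len(n2) - 1)
  qccc_state(v, n_ct1 = n1, n_ct2 = n2, gene_order = c(g1, g2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
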