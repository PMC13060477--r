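# Rule-based synthetic data with known ground-truth regulatory structure,
# and circuit-planted benchmarks with known topology and angles. Both give
# the pipeline fully controlled inputs: the rule-based generator emulates a
# two-cell-type co-culture with programmed gene-regulatory and
# communication edges, while planted circuits provide exactly recoverable
# targets for the search and refinement stages.

#' Define a ground-truth rule specification
#'
#' Describes two cell types with per-gene baseline activation probabilities
#' and a directed rule graph. In the mono condition every gene is sampled
#' independently from its baseline. In the co condition cells of the two
#' types are paired and each rule sets its target gene's activation
#' probability conditional on the source gene's current state (in the paired
#' partner cell for intercellular rules, the same cell for intracellular
#' ones). Cycles (feedback) are allowed and resolved by a fixed two-sweep
#' update.
#'
#' @param ct1_genes,ct2_genes ordered gene identifier vectors.
#' @param baseline_on_prob named numeric vector of per-gene baseline
#'   activation probabilities (all genes of both types).
#' @param rules data.frame with columns `source`, `target`, `kind`
#'   (`"intercellular"` or `"intracellular"`), `p_on_given_src_on`,
#'   `p_on_given_src_off`.
#' @param n_cells cells generated per cell type and condition.
#' @param seed integer seed.
#' @return object of class `qccc_truth_spec`.
#' @export
truth_spec <- function(ct1_genes, ct2_genes, baseline_on_prob, rules,
                       n_cells = 5000, seed = 1) {
  genes <- c(ct1_genes, ct2_genes)
  if (anyDuplicated(genes)) stop("gene names must be unique across types")
  if (!all(genes %in% names(baseline_on_prob))) {
    stop("baseline_on_prob must name every gene")
  }
  p <- baseline_on_prob[genes]
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  need <- c("source", "target", "kind", "p_on_given_src_on",
            "p_on_given_src_off")
  if (!all(need %in% names(rules))) {
    stop("rules must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(rules$source %in% genes) || !all(rules$target %in% genes)) {
    stop("rule genes must appear in the gene lists")
  }
  if (any(rules$p_on_given_src_on < 0 | rules$p_on_given_src_on > 1) ||
      any(rules$p_on_given_src_off < 0 | rules$p_on_given_src_off > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!all(rules$kind %in% c("intercellular", "intracellular"))) {
    stop("rule kind must be 'intercellular' or 'intracellular'")
  }
  structure(list(ct1_genes = ct1_genes, ct2_genes = ct2_genes,
                 baseline_on_prob = p, rules = rules,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "qccc_truth_spec")
}

#' @export
print.qccc_truth_spec <- function(x, ...) {
  cat("Ground-truth spec:", length(x$ct1_genes), "CT1 gene(s) +",
      length(x$ct2_genes), "CT2 gene(s),", nrow(x$rules), "rule(s),",
      x$n_cells, "cells per type/condition, seed", x$seed, "\n")
  print.data.frame(x$rules, row.names = FALSE)
  invisible(x)
}

#' Packaged two-cell-type benchmark specification
#'
#' The default ground-truth system: cell type 1 carries a signalling driver
#' (`g50`) and a terminal response gene (`g90`); cell type 2 carries a
#' receptor (`g60`), a two-step intracellular cascade (`g70`, `g71`) and a
#' returning ligand (`g80`). The rule graph encodes a primary
#' ligand-receptor edge `g50 -> g60`, the CT2 cascade
#' `g60 -> g70 -> g71 -> g80`, a return edge `g80 -> g90` into CT1, and
#' feedback from both `g80` and `g90` onto the driver `g50`. Defaults:
#' driver baseline 0.5, all downstream genes 0.2; every rule activates its
#' target with probability 0.9 when the source is active and 0.1 otherwise.
#'
#' @param n_cells cells per type and condition (default 5000).
#' @param seed integer seed.
#' @return a `qccc_truth_spec` on 2 + 4 genes (a 6-qubit system).
#' @export
default_truth_spec <- function(n_cells = 5000, seed = 1) {
  rules <- data.frame(
    source = c("g50", "g60", "g70", "g71", "g80", "g90", "g80"),
    target = c("g60", "g70", "g71", "g80", "g90", "g50", "g50"),
    kind = c("intercellular", "intracellular", "intracellular",
             "intracellular", "intercellular", "intracellular",
             "intercellular"),
    p_on_given_src_on = rep(0.9, 7),
    p_on_given_src_off = rep(0.1, 7),
    stringsAsFactors = FALSE
  )
  truth_spec(
    ct1_genes = c("g50", "g90"),
    ct2_genes = c("g60", "g70", "g71", "g80"),
    baseline_on_prob = c(g50 = 0.5, g90 = 0.2, g60 = 0.2, g70 = 0.2,
                         g71 = 0.2, g80 = 0.2),
    rules = rules, n_cells = n_cells, seed = seed
  )
}

#' Generate rule-based synthetic data
#'
#' Samples binary gene-activity profiles for both cell types under the mono
#' (non-interacting) and co (interacting) conditions of `spec`, and casts
#' them to raw count matrices so the full encoding path (normalization,
#' gene selection, binarization) is exercised: an active gene receives a
#' positive integer count (1 plus a Poisson draw), an inactive gene 0, and
#' two constitutively expressed background genes per cell type keep every
#' cell's total count positive.
#'
#' Co-condition sampling: cells of the two types are paired uniformly at
#' random; genes start from independent baseline draws, then every rule
#' updates its target once in rule order, and the whole pass is repeated
#' once more so feedback edges see updated sources. When several rules
#' share a target, their conditional activation probabilities combine by
#' noisy-OR.
#'
#' @param spec a `qccc_truth_spec`.
#' @param count_lambda Poisson mean of the extra counts on active genes
#'   (default 4; active count = 1 + Poisson(lambda)).
#' @return list with `counts` (named list of four cells x genes integer
#'   matrices: `ct1_mono`, `ct1_co`, `ct2_mono`, `ct2_co`, each including
#'   background genes), `tables` (the four `qccc_state_table`s over the
#'   selected genes), `pairing` (integer vector: co-condition CT1 cell `i`
#'   was observed together with CT2 cell `pairing[i]`), `ct1_genes`,
#'   `ct2_genes`, and `spec`.
#' @export
generate_rule_based <- function(spec, count_lambda = 4) {
  stopifnot(inherits(spec, "qccc_truth_spec"))
  genes <- c(spec$ct1_genes, spec$ct2_genes)
  n <- spec$n_cells
  with_seed(spec$seed, {
    base_draw <- function() {
      vapply(genes, function(g)
        stats::rbinom(n, 1L, spec$baseline_on_prob[[g]]), integer(n))
    }
    mono <- base_draw()
    co <- base_draw()
    # Random pairing of CT1 and CT2 cells: row i of `co` is one CT1 cell and
    # one CT2 cell observed together; the permutation realizes the pairing.
    pair <- sample.int(n)
    co[, spec$ct2_genes] <- co[pair, spec$ct2_genes, drop = FALSE]
    for (sweep in 1:2) {
      for (tg in unique(spec$rules$target)) {
        rr <- spec$rules[spec$rules$target == tg, , drop = FALSE]
        # noisy-OR over the rules converging on this target
        p_off <- rep(1, n)
        for (r in seq_len(nrow(rr))) {
          src_state <- co[, rr$source[r]]
          p_r <- ifelse(src_state == 1L, rr$p_on_given_src_on[r],
                        rr$p_on_given_src_off[r])
          p_off <- p_off * (1 - p_r)
        }
        co[, tg] <- stats::rbinom(n, 1L, 1 - p_off)
      }
    }
    # Undo the pairing permutation so CT2 rows are independent cells again.
    co_ct2 <- co[, spec$ct2_genes, drop = FALSE]
    co_ct2[pair, ] <- co[, spec$ct2_genes, drop = FALSE]
    make_counts <- function(bits, background) {
      m <- bits * (1L + matrix(stats::rpois(length(bits), count_lambda),
                               nrow(bits)))
      bg <- matrix(1L + stats::rpois(nrow(bits) * 2, count_lambda),
                   ncol = 2, dimnames = list(NULL, background))
      out <- cbind(m, bg)
      rownames(out) <- paste0("cell", seq_len(nrow(out)))
      out
    }
    pairing <- pair
    counts <- list(
      ct1_mono = make_counts(mono[, spec$ct1_genes, drop = FALSE],
                             c("bgA_ct1", "bgB_ct1")),
      ct1_co = make_counts(co[, spec$ct1_genes, drop = FALSE],
                           c("bgA_ct1", "bgB_ct1")),
      ct2_mono = make_counts(mono[, spec$ct2_genes, drop = FALSE],
                             c("bgA_ct2", "bgB_ct2")),
      ct2_co = make_counts(co_ct2, c("bgA_ct2", "bgB_ct2"))
    )
  })
  tables <- list(
    ct1_mono = binarize(normalize_log1p(counts$ct1_mono), spec$ct1_genes),
    ct1_co = binarize(normalize_log1p(counts$ct1_co), spec$ct1_genes),
    ct2_mono = binarize(normalize_log1p(counts$ct2_mono), spec$ct2_genes),
    ct2_co = binarize(normalize_log1p(counts$ct2_co), spec$ct2_genes)
  )
  list(counts = counts, tables = tables, pairing = pairing,
       ct1_genes = spec$ct1_genes, ct2_genes = spec$ct2_genes, spec = spec)
}

#' Generate a circuit-planted benchmark
#'
#' Applies a known topology (with known angles) to a baseline state and
#' returns the register marginals of the output as targets — either exactly
#' (zero sampling noise) or estimated from seeded multinomial draws of
#' `n_cells` bitstrings from the joint Born distribution (relative state
#' frequencies, which converge to the exact marginals as `n_cells` grows).
#'
#' @param tau planted `qccc_topology`.
#' @param psi1,psi2 baseline amplitude vectors for the two registers.
#' @param exact if `TRUE` (default) targets are the exact output marginals;
#'   otherwise empirical distributions of `n_cells` sampled cells.
#' @param n_cells number of sampled cells per register (sampled mode).
#' @param seed seed for sampled mode.
#' @return list: `initial` (the baseline `qccc_state`), `q_ct1`, `q_ct2`
#'   (target `qccc_probdist`s), `tables` (per-register state tables, sampled
#'   mode only), and `tau`.
#' @export
generate_planted_circuit <- function(tau, psi1, psi2, exact = TRUE,
                                     n_cells = 10000, seed = 1) {
  initial <- tensor_initial_state(psi1, psi2)
  out <- simulate_circuit(tau, initial)
  if (exact) {
    return(list(initial = initial, q_ct1 = marginal(out, "CT1"),
                q_ct2 = marginal(out, "CT2"), tables = NULL, tau = tau))
  }
  n1 <- attr(initial, "n_ct1"); n2 <- attr(initial, "n_ct2")
  p_joint <- Mod(unclass(out))^2
  draws <- with_seed(seed,
                     sample.int(length(p_joint), n_cells, replace = TRUE,
                                prob = p_joint)) - 1L
  s1 <- bitwShiftR(draws, n2)
  s2 <- bitwAnd(draws, 2^n2 - 1L)
  go <- attr(initial, "gene_order")
  tab_from <- function(states, d, gene_order) {
    tt <- table(index_to_bits(states, d))
    state_table(stats::setNames(as.integer(tt), names(tt)), gene_order)
  }
  t1 <- tab_from(s1, n1, go[seq_len(n1)])
  t2 <- tab_from(s2, n2, go[n1 + seq_len(n2)])
  # Sampled targets are the empirical Born marginals (relative frequencies),
  # the finite-sample estimate of what exact mode returns. The squared-L2
  # encoding convention belongs to the expression pipeline (see
  # target_distribution()), not to this generator's contract.
  freq_dist <- function(tab, d) {
    p <- numeric(2^d)
    p[bits_to_index(names(tab$counts)) + 1L] <- tab$counts / tab$n_cells
    structure(p, gene_order = tab$gene_order, class = "qccc_probdist")
  }
  list(initial = initial, q_ct1 = freq_dist(t1, n1),
       q_ct2 = freq_dist(t2, n2),
       tables = list(ct1 = t1, ct2 = t2), tau = tau)
}
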