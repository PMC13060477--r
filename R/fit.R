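# The model-fitting surface. qccc() runs the whole inference: encode the
# four input populations, build the baseline state and target distributions,
# propose candidate gates from the density difference, search the entangling
# topology at fixed pi/2 angles, refine the angles continuously, and dissect
# the fitted circuit by sequential ablation.

#' Fit a cell-cell communication circuit model
#'
#' Learns an entangling controlled-RX circuit that maps the binarized
#' expression-state distribution of two non-interacting cell populations
#' onto their interacting-state distribution, then ranks each gate
#' (interaction) by its contribution to the distributional shift.
#'
#' Inputs may be raw count matrices (cells x genes; they are total-count
#' normalized, log1p-transformed, restricted to the selected genes and
#' binarized at `threshold`) or precomputed binary state tables from
#' [binarize()].
#'
#' @param ct1_mono,ct1_co,ct2_mono,ct2_co the four input populations: cell
#'   types 1 and 2 under the non-interacting (mono) and interacting (co)
#'   conditions; each a counts matrix or a `qccc_state_table`.
#' @param genes_ct1,genes_ct2 gene selections defining the two registers
#'   (required for matrix input; ignored for state tables, which carry their
#'   own gene order).
#' @param threshold binarization threshold (see [binarize()]).
#' @param target_total total-count normalization target (see
#'   [normalize_log1p()]).
#' @param delta_cutoff density-difference cutoff for candidate pruning
#'   (default 0.01, see [gate_candidates()]).
#' @param algorithm topology search strategy: `"multi_epoch"` (default),
#'   `"nwise"`, or `"qubo"`.
#' @param optimizer angle refinement optimizer (see [optimize_angles()]).
#' @param refine_angles if `FALSE`, skip continuous refinement and keep the
#'   fixed `pi/2` search angles.
#' @param eps KL smoothing constant.
#' @param seed integer seed covering all stochastic stages.
#' @param search_control named list of extra arguments for the search
#'   function (e.g. `epochs`, `n`, `max_gates`, `improvement_tol`,
#'   `occam_tol`, `backend`).
#' @return an object of class `qccc`; see [print.qccc()], [summary.qccc()],
#'   [coef.qccc()], [predict.qccc()], [residuals.qccc()], [simulate.qccc()]
#'   and [plot.qccc()]. Components include the baseline state (`initial`),
#'   target distributions, candidate set, search result, refinement result,
#'   final `topology`, `ablation` table and interaction `network`.
#' @examples
#' # recover a planted communication gate from sampled co-culture states
#' planted <- generate_planted_circuit(
#'   topology(control = 0, target = 2, angle = pi / 2),
#'   amplitudes_from_counts(state_table(c("01" = 3L, "10" = 7L),
#'                                      c("gA", "gB"))),
#'   amplitudes_from_counts(state_table(c("0" = 9L, "1" = 1L), "gC")),
#'   exact = FALSE, n_cells = 2000, seed = 7
#' )
#' fit <- qccc(ct1_mono = state_table(c("01" = 3L, "10" = 7L), c("gA", "gB")),
#'             ct1_co = planted$tables$ct1,
#'             ct2_mono = state_table(c("0" = 9L, "1" = 1L), "gC"),
#'             ct2_co = planted$tables$ct2, seed = 1)
#' print(fit)
#' coef(fit)  # the planted gA -> gC edge, angle near pi/2
#' @export
qccc <- function(ct1_mono, ct1_co, ct2_mono, ct2_co,
                 genes_ct1 = NULL, genes_ct2 = NULL, threshold = 0,
                 target_total = NULL, delta_cutoff = 0.01,
                 algorithm = c("multi_epoch", "nwise", "qubo"),
                 optimizer = c("lbfgsb", "neldermead"), refine_angles = TRUE,
                 eps = 1e-10, seed = 1, search_control = list()) {
  algorithm <- match.arg(algorithm)
  optimizer <- match.arg(optimizer)
  cl <- match.call()

  as_table <- function(x, genes, label) {
    if (inherits(x, "qccc_state_table")) return(x)
    if (is.null(genes)) {
      stop("gene selection required for matrix input `", label, "`")
    }
    binarize(normalize_log1p(x, target_total = target_total), genes,
             threshold = threshold)
  }
  t1_mo <- as_table(ct1_mono, genes_ct1, "ct1_mono")
  t1_co <- as_table(ct1_co, genes_ct1, "ct1_co")
  t2_mo <- as_table(ct2_mono, genes_ct2, "ct2_mono")
  t2_co <- as_table(ct2_co, genes_ct2, "ct2_co")
  if (!identical(t1_mo$gene_order, t1_co$gene_order) ||
      !identical(t2_mo$gene_order, t2_co$gene_order)) {
    stop("mono and co state tables must share the same gene order")
  }

  psi1 <- amplitudes_from_counts(t1_mo)
  psi2 <- amplitudes_from_counts(t2_mo)
  initial <- tensor_initial_state(psi1, psi2)
  q_ct1 <- target_distribution(t1_co)
  q_ct2 <- target_distribution(t2_co)
  # Interacting global state for pruning: tensor product of the per-type
  # co-condition amplitude vectors, mirroring the baseline construction.
  psi_co <- tensor_initial_state(amplitudes_from_counts(t1_co),
                                 amplitudes_from_counts(t2_co))
  delta <- density_delta(initial, psi_co)
  candidates <- gate_candidates(delta, cutoff = delta_cutoff)

  search_args <- c(list(candidates = candidates, initial = initial,
                        q_ct1 = q_ct1, q_ct2 = q_ct2, eps = eps),
                   search_control)
  if (algorithm %in% c("multi_epoch", "qubo") &&
      !("seed" %in% names(search_control))) {
    search_args$seed <- seed
  }
  search <- do.call(switch(algorithm,
                           multi_epoch = multi_epoch_search,
                           nwise = nwise_local_search,
                           qubo = qubo_select_and_order),
                    search_args)

  if (refine_angles && nrow(search$topology) > 0) {
    refinement <- optimize_angles(search$topology, initial, q_ct1, q_ct2,
                                  optimizer = optimizer, seed = seed,
                                  eps = eps)
    tau <- refinement$topology
  } else {
    refinement <- NULL
    tau <- search$topology
  }

  ablation <- sequential_contribution(tau, initial, q_ct1, q_ct2, eps = eps)
  network <- to_network(ablation)
  final_cost <- circuit_cost(tau, initial, q_ct1, q_ct2, eps = eps)

  structure(list(
    call = cl,
    gene_map = attr(initial, "gene_order"),
    n_ct1 = attr(initial, "n_ct1"), n_ct2 = attr(initial, "n_ct2"),
    tables = list(ct1_mono = t1_mo, ct1_co = t1_co, ct2_mono = t2_mo,
                  ct2_co = t2_co),
    initial = initial, q_ct1 = q_ct1, q_ct2 = q_ct2,
    density_delta = delta, candidates = candidates,
    search = search, refinement = refinement,
    topology = tau, ablation = ablation, network = network,
    kl = list(baseline = search$kl_initial, after_search = search$kl_final,
              final = final_cost$total, ct1 = final_cost$kl_ct1,
              ct2 = final_cost$kl_ct2),
    algorithm = algorithm, optimizer = optimizer, eps = eps, seed = seed
  ), class = "qccc")
}

#' @describeIn qccc Compact description of a fitted model.
#' @param x,object a fitted `qccc` model.
#' @param ... unused.
#' @export
print.qccc <- function(x, ...) {
  cat("Cell-cell communication circuit model\n")
  cat(sprintf("  Registers: CT1 = %d qubit(s) [%s], CT2 = %d qubit(s) [%s]\n",
              x$n_ct1, paste(x$gene_map[seq_len(x$n_ct1)], collapse = ", "),
              x$n_ct2,
              paste(x$gene_map[x$n_ct1 + seq_len(x$n_ct2)], collapse = ", ")))
  cat(sprintf("  Search: %s over %d candidate gate(s); topology has %d gate(s)\n",
              x$algorithm, nrow(x$candidates), nrow(x$topology)))
  cat(sprintf("  KL: baseline %.4g -> search %.4g -> refined %.4g\n",
              x$kl$baseline, x$kl$after_search, x$kl$final))
  invisible(x)
}

#' @describeIn qccc Full summary: gates, contributions, network edges.
#' @export
summary.qccc <- function(object, ...) {
  edges <- igraph::as_data_frame(object$network, what = "edges")
  out <- list(call = object$call, kl = object$kl,
              n_candidates = nrow(object$candidates),
              topology = object$topology, ablation = object$ablation,
              edges = edges)
  class(out) <- "summary.qccc"
  out
}

#' @export
print.summary.qccc <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\nKL divergence: baseline %.4g, final %.4g (%d candidate gates considered)\n\n",
              x$kl$baseline, x$kl$final, x$n_candidates))
  print(x$ablation)
  if (nrow(x$edges) > 0) {
    cat("\nInteraction network edges:\n")
    print.data.frame(x$edges[, c("from", "to", "class", "kl_delta")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn qccc Optimized gate angles (radians), named
#'   `"source->target"` by gene.
#' @export
coef.qccc <- function(object, ...) {
  tau <- object$topology
  stats::setNames(tau$angle,
                  paste0(object$gene_map[tau$control + 1L], "->",
                         object$gene_map[tau$target + 1L]))
}

#' @describeIn qccc Fitted register marginal distributions (the model's
#'   prediction of the interacting-state distributions).
#' @param register `"CT1"`, `"CT2"`, or `"both"` (default).
#' @export
predict.qccc <- function(object, register = c("both", "CT1", "CT2"), ...) {
  register <- match.arg(register)
  out_state <- simulate_circuit(object$topology, object$initial)
  if (register == "both") {
    list(CT1 = marginal(out_state, "CT1"), CT2 = marginal(out_state, "CT2"))
  } else {
    marginal(out_state, register)
  }
}

#' @describeIn qccc Fitted minus target marginal probabilities, per register.
#' @export
residuals.qccc <- function(object, ...) {
  p <- predict(object, "both")
  list(CT1 = as.numeric(p$CT1) - as.numeric(object$q_ct1),
       CT2 = as.numeric(p$CT2) - as.numeric(object$q_ct2))
}

#' @describeIn qccc Sample synthetic cells from the fitted joint Born
#'   distribution: each draw is a pair of register bitstrings.
#' @param nsim number of replicate datasets.
#' @param seed seed for the draws.
#' @param n_cells cells per replicate.
#' @export
simulate.qccc <- function(object, nsim = 1, seed = NULL, n_cells = 1000,
                          ...) {
  out_state <- simulate_circuit(object$topology, object$initial)
  p <- Mod(unclass(out_state))^2
  n1 <- object$n_ct1; n2 <- object$n_ct2
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      idx <- sample.int(length(p), n_cells, replace = TRUE, prob = p) - 1L
      data.frame(ct1_state = index_to_bits(bitwShiftR(idx, n2), n1),
                 ct2_state = index_to_bits(bitwAnd(idx, 2^n2 - 1L), n2),
                 stringsAsFactors = FALSE)
    })
  })
}

#' @describeIn qccc Diagnostic plot: search convergence trace and fitted
#'   versus target register marginals.
#' @export
plot.qccc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  tr <- x$search$trace
  graphics::plot(tr$iteration, tr$cost, type = "b", pch = 16,
                 xlab = "Search iteration / epoch", ylab = "Total KL",
                 main = paste("Convergence (", x$algorithm, ")", sep = ""))
  pred <- predict(x, "both")
  for (reg in c("CT1", "CT2")) {
    q <- if (reg == "CT1") x$q_ct1 else x$q_ct2
    d <- round(log2(length(q)))
    m <- rbind(target = as.numeric(q), fitted = as.numeric(pred[[reg]]))
    graphics::barplot(m, beside = TRUE,
                      names.arg = index_to_bits(seq_len(2^d) - 1, d),
                      las = 2, col = c("grey30", "steelblue"),
                      main = paste(reg, "marginal"), ylab = "Probability")
    graphics::legend("topright", legend = c("target", "fitted"),
                     fill = c("grey30", "steelblue"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
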