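# Discrete topology search over the pruned candidate set: which gates, in
# which order, minimize the marginal-KL cost at the fixed search angle pi/2.
# Three interchangeable strategies share one result contract:
#   - n-wise greedy local search (insertion/deletion moves, best improvement)
#   - multi-epoch stochastic forward construction with Occam pruning
#   - QUBO gate selection plus exhaustive ordering of the selected set.

SEARCH_ANGLE <- pi / 2

# Shared closure: cost of a sequence of candidate row indices. Works on the
# bare amplitude vector (no per-call object construction) because the search
# loops evaluate it many thousands of times.
make_cost_fn <- function(candidates, initial, q_ct1, q_ct2, eps,
                         angle = SEARCH_ANGLE) {
  n1 <- attr(initial, "n_ct1"); n2 <- attr(initial, "n_ct2")
  d <- n1 + n2
  ctrl <- as.integer(candidates$control)
  tgt <- as.integer(candidates$target)
  amp0 <- unclass(initial)
  q1 <- as.numeric(q_ct1); q2 <- as.numeric(q_ct2)
  qt1 <- (q1 + eps) / sum(q1 + eps)
  qt2 <- (q2 + eps) / sum(q2 + eps)
  n_evals <- 0L
  cost_of <- function(seq_idx) {
    n_evals <<- n_evals + 1L
    amp <- amp0
    for (i in seq_idx) amp <- crx_kernel(amp, d, ctrl[i], tgt[i], angle)
    p <- Mod(amp)^2
    m <- matrix(p, nrow = 2^n2)
    p1 <- colSums(m); p2 <- rowSums(m)
    pt1 <- (p1 + eps) / sum(p1 + eps)
    pt2 <- (p2 + eps) / sum(p2 + eps)
    max(0, sum(pt1 * (log(pt1) - log(qt1)))) +
      max(0, sum(pt2 * (log(pt2) - log(qt2))))
  }
  list(cost = cost_of, evals = function() n_evals)
}

search_result <- function(seq_idx, candidates, kl_initial, kl_final, trace,
                          algorithm, n_evals) {
  tau <- topology(control = candidates$control[seq_idx],
                  target = candidates$target[seq_idx], angle = SEARCH_ANGLE)
  structure(list(topology = tau, sequence = seq_idx, kl_initial = kl_initial,
                 kl_final = kl_final, trace = trace, algorithm = algorithm,
                 n_evals = n_evals),
            class = "qccc_search")
}

#' @export
print.qccc_search <- function(x, ...) {
  cat(sprintf("Topology search (%s): %d gate(s), KL %.6g -> %.6g (%d cost evaluations)\n",
              x$algorithm, nrow(x$topology), x$kl_initial, x$kl_final,
              x$n_evals))
  invisible(x)
}

trace_row <- function(iteration, cost, move) {
  data.frame(iteration = iteration, cost = cost, move = move,
             stringsAsFactors = FALSE)
}

#' Greedy n-wise local search for the entangling topology
#'
#' Best-improvement local search over ordered gate sequences built from the
#' candidate set. Each iteration enumerates every move touching up to `n`
#' gates — inserting a candidate at any position (including appending) and
#' deleting an existing gate — applies the single best cost-reducing move,
#' and stops when no move improves the cost by more than `improvement_tol`.
#' Single-gate moves are tried first; compound moves of up to `n` elementary
#' steps are explored only once no single move improves, which keeps typical
#' iterations cheap while still allowing paired insert+delete substitutions.
#'
#' @param candidates a `qccc_candidates` (or data.frame with `control`,
#'   `target` columns).
#' @param initial baseline `qccc_state`.
#' @param q_ct1,q_ct2 target register distributions.
#' @param n move breadth: maximum number of elementary moves combined in one
#'   accepted step (default 2).
#' @param improvement_tol minimum cost decrease to accept a move.
#' @param max_gates upper bound on topology length.
#' @param eps KL smoothing constant.
#' @return a `qccc_search` result: `topology` (all angles `pi/2`),
#'   `kl_initial`, `kl_final`, and a `trace` of accepted moves. Deterministic
#'   for fixed inputs.
#' @export
nwise_local_search <- function(candidates, initial, q_ct1, q_ct2, n = 2,
                               improvement_tol = 1e-6, max_gates = 10,
                               eps = 1e-10) {
  stopifnot(n >= 1, improvement_tol >= 0)
  fn <- make_cost_fn(candidates, initial, q_ct1, q_ct2, eps)
  seq_idx <- integer(0)
  cur <- fn$cost(seq_idx)
  kl_initial <- cur
  trace <- trace_row(0L, cur, "baseline")
  nc <- nrow(candidates)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    best <- best_move(seq_idx, cur, nc, max_gates, fn$cost, depth = 1L)
    if ((cur - best$cost) <= improvement_tol && n >= 2) {
      best <- best_move(seq_idx, cur, nc, max_gates, fn$cost, depth = 2L)
    }
    if ((cur - best$cost) <= improvement_tol) break
    seq_idx <- best$seq
    cur <- best$cost
    trace <- rbind(trace, trace_row(iter, cur, best$move))
  }
  search_result(seq_idx, candidates, kl_initial, cur, trace, "nwise",
                fn$evals())
}

# Enumerate 1-move neighbors of seq (insertions of any candidate at any
# position, deletions of any gate); depth 2 chains a second elementary move
# from each 1-move neighbor. Returns the best neighbor found.
best_move <- function(seq_idx, cur_cost, nc, max_gates, cost_of,
                      depth = 1L) {
  neighbors1 <- function(s) {
    out <- list()
    if (length(s) < max_gates && nc > 0) {
      for (c in seq_len(nc)) {
        for (pos in seq_len(length(s) + 1L)) {
          out[[length(out) + 1L]] <- append(s, c, after = pos - 1L)
        }
      }
    }
    for (pos in seq_along(s)) out[[length(out) + 1L]] <- s[-pos]
    out
  }
  frontier <- neighbors1(seq_idx)
  if (depth >= 2L) {
    lvl2 <- unlist(lapply(frontier, neighbors1), recursive = FALSE)
    frontier <- c(frontier, lvl2)
  }
  if (length(frontier) == 0) {
    return(list(seq = seq_idx, cost = cur_cost, move = "none"))
  }
  keys <- vapply(frontier, paste, character(1), collapse = ",")
  frontier <- frontier[!duplicated(keys)]
  frontier <- frontier[vapply(frontier, function(s)
    paste(s, collapse = ",") != paste(seq_idx, collapse = ","), logical(1))]
  costs <- vapply(frontier, cost_of, numeric(1))
  b <- which.min(costs)
  list(seq = frontier[[b]], cost = costs[b],
       move = sprintf("depth<=%d move to [%s]", depth,
                      paste(frontier[[b]], collapse = ",")))
}

#' Multi-epoch stochastic greedy construction with Occam pruning
#'
#' Each epoch shuffles the candidate set (seeded) and opens the sequence
#' with the head of the shuffled order — the epoch's random starting point.
#' Construction then repeatedly inserts the cost-minimizing (candidate,
#' position) pair, candidates drawn with replacement from the full set
#' (duplicate gates are legal in a topology), while the improvement exceeds
#' `improvement_tol` and the topology is shorter than `max_gates`. Each
#' construction phase is followed by the Occam parsimony pass — any gate
#' whose removal worsens the cost by at most `occam_tol` is removed,
#' preferring removals that reduce the cost — and construction and pruning
#' alternate until neither changes the sequence. The best sequence across
#' epochs is returned.
#'
#' @inheritParams nwise_local_search
#' @param epochs number of stochastic restarts (default 10).
#' @param occam_tol maximum cost increase tolerated when removing a gate in
#'   the parsimony pass.
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @return a `qccc_search` result.
#' @export
multi_epoch_search <- function(candidates, initial, q_ct1, q_ct2,
                               epochs = 10, max_gates = 10,
                               improvement_tol = 1e-6, occam_tol = 1e-4,
                               seed = 1, eps = 1e-10) {
  stopifnot(epochs >= 1)
  fn <- make_cost_fn(candidates, initial, q_ct1, q_ct2, eps)
  base <- fn$cost(integer(0))
  nc <- nrow(candidates)
  trace <- trace_row(0L, base, "baseline")

  construct <- function(s, cur) {
    while (length(s) < max_gates && nc > 0) {
      best_s <- NULL; best_cost <- Inf
      for (c in seq_len(nc)) {
        for (p in seq_len(length(s) + 1L)) {
          cc <- fn$cost(append(s, c, after = p - 1L))
          if (cc < best_cost) {
            best_cost <- cc; best_s <- append(s, c, after = p - 1L)
          }
        }
      }
      if ((cur - best_cost) <= improvement_tol) break
      s <- best_s; cur <- best_cost
    }
    list(s = s, cost = cur)
  }
  prune <- function(s, cur) {
    while (length(s) > 0) {
      costs <- vapply(seq_along(s), function(p) fn$cost(s[-p]), numeric(1))
      b <- which.min(costs)
      if (costs[b] <= cur + occam_tol) {
        s <- s[-b]; cur <- costs[b]
      } else break
    }
    list(s = s, cost = cur)
  }

  best_seq <- integer(0); best_cost <- base
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      order_e <- if (nc > 0) sample.int(nc) else integer(0)
      # Random starting point: the head of this epoch's shuffled order opens
      # the sequence unconditionally, so different epochs explore different
      # constructions; a harmful start is removed by the Occam pass or loses
      # in the cross-epoch comparison.
      if (length(order_e) > 0 && max_gates >= 1) {
        s <- order_e[1]; cur <- fn$cost(s)
      } else {
        s <- integer(0); cur <- base
      }
      # Alternate construction and parsimony pruning to a fixed point.
      repeat {
        r <- construct(s, cur)
        r <- prune(r$s, r$cost)
        if (identical(r$s, s) && r$cost >= cur - 1e-15) break
        s <- r$s; cur <- r$cost
      }
      if (cur < best_cost - 1e-15) {
        best_seq <- s; best_cost <- cur
      }
      trace <- rbind(trace, trace_row(e, cur,
                                      sprintf("epoch %d: %d gates", e,
                                              length(s))))
    }
  })
  search_result(best_seq, candidates, base, best_cost, trace, "multi_epoch",
                fn$evals())
}

#' QUBO gate selection with classical ordering
#'
#' Decouples the search into (1) an unordered gate-selection stage encoded as
#' a quadratic unconstrained binary optimization problem and (2) exhaustive
#' ordering of the selected gates. The QUBO coefficients are measured by
#' simulation: linear terms `a_g = L({g}) - L(empty)` and pairwise terms
#' `b_gh = L({g, h}) - L({g}) - L({h}) + L(empty)` with `g` before `h` in
#' candidate-rank order (the fixed canonical order for pairwise evaluation).
#'
#' @inheritParams multi_epoch_search
#' @param backend QUBO solver: `"exact"` (full enumeration, requires at most
#'   20 candidates), `"anneal"` (seeded simulated annealing), or `"auto"`
#'   (exact when the pool allows it, otherwise annealing).
#' @param cardinality_penalty if positive, adds
#'   `lambda * (sum(x) - max_gates)^2` to the QUBO objective.
#' @return a `qccc_search` result. Errors if more than 8 gates are selected
#'   (the ordering stage is exhaustive); use the local or multi-epoch search
#'   for larger topologies.
#' @export
qubo_select_and_order <- function(candidates, initial, q_ct1, q_ct2,
                                  backend = c("auto", "exact", "anneal"),
                                  max_gates = 10, cardinality_penalty = 0,
                                  seed = 1, eps = 1e-10) {
  backend <- match.arg(backend)
  nc <- nrow(candidates)
  if (backend == "auto") backend <- if (nc <= 20) "exact" else "anneal"
  if (nc > 30) {
    warning("candidate set exceeds 30 gates; the QUBO stage becomes ",
            "intractable and the local searches are recommended")
  }
  fn <- make_cost_fn(candidates, initial, q_ct1, q_ct2, eps)
  base <- fn$cost(integer(0))
  if (nc == 0) {
    return(search_result(integer(0), candidates, base, base,
                         trace_row(0L, base, "baseline"), "qubo", fn$evals()))
  }
  a <- vapply(seq_len(nc), function(g) fn$cost(g) - base, numeric(1))
  b <- matrix(0, nc, nc)
  if (nc >= 2) {
    for (g in seq_len(nc - 1)) {
      for (h in (g + 1):nc) {
        b[g, h] <- fn$cost(c(g, h)) - a[g] - a[h] - base
      }
    }
  }
  qubo_obj <- function(x) {
    e <- sum(a * x) + drop(x %*% b %*% x)
    if (cardinality_penalty > 0) {
      e <- e + cardinality_penalty * (sum(x) - max_gates)^2
    }
    e
  }
  x <- switch(backend,
              exact = qubo_exact(qubo_obj, nc),
              anneal = qubo_anneal(qubo_obj, nc, seed = seed))
  sel <- which(x == 1)
  k <- length(sel)
  if (k > 8) {
    stop("QUBO selection returned ", k, " gates; exhaustive ordering is ",
         "limited to 8. Use nwise_local_search() or multi_epoch_search().")
  }
  # Ordering stage: evaluate every permutation of the selected set; ties are
  # broken toward candidate-rank order.
  best_seq <- sel; best_cost <- fn$cost(sel)
  if (k >= 2) {
    for (p in permutations_of(sel)) {
      cp <- fn$cost(p)
      if (cp < best_cost - 1e-15) {
        best_seq <- p; best_cost <- cp
      }
    }
  }
  trace <- rbind(trace_row(0L, base, "baseline"),
                 trace_row(1L, best_cost,
                           sprintf("qubo selected %d gate(s)", k)))
  search_result(best_seq, candidates, base, best_cost, trace, "qubo",
                fn$evals())
}

# All permutations of a vector (list); first element is the input order.
permutations_of <- function(v) {
  k <- length(v)
  if (k <= 1) return(list(v))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), v)
  c(list(v), out[vapply(out, function(p) !identical(p, v), logical(1))])
}

# Exact QUBO minimization by enumeration (chunked); nc <= 20.
qubo_exact <- function(obj, nc) {
  if (nc > 20) stop("exact QUBO enumeration limited to 20 candidates")
  best_x <- integer(nc); best_e <- obj(best_x)
  for (m in seq_len(2^nc - 1)) {
    x <- qubit_bit(m, 0:(nc - 1L), nc)
    e <- obj(x)
    if (e < best_e - 1e-15) {
      best_e <- e; best_x <- x
    }
  }
  best_x
}

# Seeded simulated annealing over bit flips.
qubo_anneal <- function(obj, nc, seed = 1, n_sweeps = 200, t_start = 1,
                        t_end = 1e-4) {
  with_seed(seed, {
    x <- stats::rbinom(nc, 1, 0.5)
    e <- obj(x)
    best_x <- x; best_e <- e
    temps <- exp(seq(log(t_start), log(t_end), length.out = n_sweeps))
    for (t in temps) {
      for (i in sample.int(nc)) {
        xn <- x; xn[i] <- 1L - xn[i]
        en <- obj(xn)
        if (en < e || stats::runif(1) < exp((e - en) / t)) {
          x <- xn; e <- en
          if (e < best_e) {
            best_x <- x; best_e <- e
          }
        }
      }
    }
    best_x
  })
}

#' Dispatch a topology search by name
#'
#' @inheritParams nwise_local_search
#' @param algorithm `"multi_epoch"` (default), `"nwise"`, or `"qubo"`.
#' @param ... passed to the selected search function.
#' @return a `qccc_search` result.
#' @export
search_topology <- function(candidates, initial, q_ct1, q_ct2,
                            algorithm = c("multi_epoch", "nwise", "qubo"),
                            ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         multi_epoch = multi_epoch_search(candidates, initial, q_ct1, q_ct2,
                                          ...),
         nwise = nwise_local_search(candidates, initial, q_ct1, q_ct2, ...),
         qubo = qubo_select_and_order(candidates, initial, q_ct1, q_ct2, ...))
}
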