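tv_distance <- function(t1, t2) {
  states <- union(names(t1$counts), names(t2$counts))
  p <- setNames(numeric(length(states)), states)
  q <- p
  p[names(t1$counts)] <- t1$counts / t1$n_cells
  q[names(t2$counts)] <- t2$counts / t2$n_cells
  sum(abs(p - q)) / 2
}

test_that("without rules, mono and co conditions share one distribution", {
  spec <- truth_spec(
    ct1_genes = c("g1", "g2"), ct2_genes = c("g3", "g4"),
    baseline_on_prob = c(g1 = 0.5, g2 = 0.3, g3 = 0.6, g4 = 0.2),
    rules = data.frame(source = character(0), target = character(0),
                       kind = character(0), p_on_given_src_on = numeric(0),
                       p_on_given_src_off = numeric(0)),
    n_cells = 5000, seed = 21
  )
  dat <- generate_rule_based(spec)
  expect_lt(tv_distance(dat$tables$ct1_mono, dat$tables$ct1_co), 0.05)
  expect_lt(tv_distance(dat$tables$ct2_mono, dat$tables$ct2_co), 0.05)
})

test_that("a single rule produces the law-of-total-probability marginal", {
  spec <- truth_spec(
    ct1_genes = "g50", ct2_genes = "g60",
    baseline_on_prob = c(g50 = 0.5, g60 = 0.2),
    rules = data.frame(source = "g50", target = "g60",
                       kind = "intercellular", p_on_given_src_on = 0.9,
                       p_on_given_src_off = 0.1),
    n_cells = 5000, seed = 17
  )
  dat <- generate_rule_based(spec)
  p_on <- sum(dat$tables$ct2_co$counts[names(dat$tables$ct2_co$counts) ==
                                         "1"]) / spec$n_cells
  expect_equal(p_on, 0.5, tolerance = 0.03)   # 0.5 * 0.9 + 0.5 * 0.1
  # mono condition keeps the baseline rate
  p_mono <- sum(dat$tables$ct2_mono$counts[names(dat$tables$ct2_mono$counts)
                                           == "1"]) / spec$n_cells
  expect_equal(p_mono, 0.2, tolerance = 0.03)
})

test_that("generation is reproducible under a fixed seed", {
  spec <- default_truth_spec(n_cells = 500, seed = 33)
  d1 <- generate_rule_based(spec)
  d2 <- generate_rule_based(spec)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$tables, d2$tables)
  d3 <- generate_rule_based(default_truth_spec(n_cells = 500, seed = 34))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("the packaged benchmark spec has the documented structure", {
  spec <- default_truth_spec(n_cells = 5000, seed = 1)
  expect_length(spec$ct1_genes, 2)
  expect_length(spec$ct2_genes, 4)
  expect_true(all(spec$rules$p_on_given_src_on > spec$rules$p_on_given_src_off))
  # the interaction shifts the distribution of the CT1 response gene g90
  dat <- generate_rule_based(spec)
  marg <- function(tab, gene) {
    pos <- match(gene, tab$gene_order)
    on <- substr(names(tab$counts), pos, pos) == "1"
    sum(tab$counts[on]) / tab$n_cells
  }
  expect_gt(abs(marg(dat$tables$ct1_co, "g90") -
                  marg(dat$tables$ct1_mono, "g90")), 0.05)
})

test_that("programmed conditional dependencies appear in the co data", {
  spec <- default_truth_spec(n_cells = 5000, seed = 7)
  dat <- generate_rule_based(spec)
  bits <- function(counts_mat, genes) {
    (counts_mat[, genes, drop = FALSE] > 0) + 0L
  }
  b1 <- bits(dat$counts$ct1_co, spec$ct1_genes)
  b2 <- bits(dat$counts$ct2_co, spec$ct2_genes)[dat$pairing, , drop = FALSE]
  joint <- cbind(b1, b2)  # row i: CT1 cell i with its paired CT2 cell
  for (r in seq_len(nrow(spec$rules))) {
    src <- joint[, spec$rules$source[r]]
    tgt <- joint[, spec$rules$target[r]]
    effect <- mean(tgt[src == 1]) - mean(tgt[src == 0])
    expect_gt(effect, 0)
  }
})

test_that("planted-circuit targets match exact marginals and sampling", {
  psi1 <- random_amplitudes(1, 41, prefix = "a")
  psi2 <- random_amplitudes(2, 42, prefix = "b")
  # identity topology: targets are the baseline marginals
  pl0 <- generate_planted_circuit(topology(), psi1, psi2, exact = TRUE)
  expect_equal(as.numeric(pl0$q_ct1), as.numeric(psi1)^2, tolerance = 1e-12)
  expect_equal(as.numeric(pl0$q_ct2), as.numeric(psi2)^2, tolerance = 1e-12)
  # CRX(pi/2) on |10>: the target register becomes uniform
  e1 <- structure(c(0, 1), gene_order = "gA")
  e0 <- structure(c(1, 0), gene_order = "gB")
  pl1 <- generate_planted_circuit(topology(0, 1, pi / 2), e1, e0,
                                  exact = TRUE)
  expect_equal(as.numeric(pl1$q_ct2), c(0.5, 0.5), tolerance = 1e-12)
  # sampled mode converges to the exact targets
  tau <- topology(c(0, 1), c(2, 0), c(1.2, 0.6))
  exact <- generate_planted_circuit(tau, random_amplitudes(2, 43, "a"),
                                    random_amplitudes(1, 44, "b"),
                                    exact = TRUE)
  sampled <- generate_planted_circuit(tau, random_amplitudes(2, 43, "a"),
                                      random_amplitudes(1, 44, "b"),
                                      exact = FALSE, n_cells = 10000,
                                      seed = 9)
  tv1 <- sum(abs(as.numeric(exact$q_ct1) - as.numeric(sampled$q_ct1))) / 2
  tv2 <- sum(abs(as.numeric(exact$q_ct2) - as.numeric(sampled$q_ct2))) / 2
  expect_lt(tv1, 0.02)
  expect_lt(tv2, 0.02)
})

test_that("spec validation rejects malformed inputs", {
  expect_error(truth_spec("g1", "g1", c(g1 = 0.5),
                          data.frame(source = "g1", target = "g1",
                                     kind = "intracellular",
                                     p_on_given_src_on = 0.9,
                                     p_on_given_src_off = 0.1)),
               "unique")
  expect_error(truth_spec("g1", "g2", c(g1 = 1.5, g2 = 0.1),
                          data.frame(source = character(0),
                                     target = character(0),
                                     kind = character(0),
                                     p_on_given_src_on = numeric(0),
                                     p_on_given_src_off = numeric(0))),
               "\\[0, 1\\]")
})
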