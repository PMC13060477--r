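# File interfaces: count matrices (Matrix Market or dense delimited), gene
# lists, topology JSON, OpenQASM export, state-table/distribution TSVs, and
# the on-disk form of a synthetic dataset.

#' Read a count matrix in Matrix Market format
#'
#' Expects the 10x-style triplet: an `.mtx` file of genes x cells (or
#' cells x genes) counts plus two annotation files with one identifier per
#' line, features (genes) and barcodes (cells).
#'
#' @param mtx_path path to the Matrix Market file.
#' @param features_path path to the gene identifier file (first column used
#'   if tab-separated).
#' @param barcodes_path path to the cell identifier file.
#' @param genes_in_rows if `TRUE` (default, the 10x convention) the matrix
#'   rows are genes and it is transposed to cells x genes.
#' @return dense integer matrix, cells x genes, dimnames set.
#' @export
read_counts_mtx <- function(mtx_path, features_path, barcodes_path,
                            genes_in_rows = TRUE) {
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(features_path, sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
  cells <- utils::read.table(barcodes_path, sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
  m <- as.matrix(m)
  if (genes_in_rows) m <- t(m)
  if (nrow(m) != length(cells) || ncol(m) != length(feats)) {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match annotations (", length(cells), " cells, ",
         length(feats), " genes)")
  }
  dimnames(m) <- list(cells, feats)
  m
}

#' Read a dense delimited count matrix
#'
#' Cells x genes with a header row of gene identifiers; optional first
#' column of cell identifiers.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension; `sep`
#'   overrides).
#' @param sep field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @return numeric matrix, cells x genes.
#' @export
read_counts_dense <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) > 1 && is.character(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "numeric"
  m
}

#' Read a gene list (one identifier per line)
#'
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write a state table or probability distribution as TSV
#'
#' Two columns: the state bitstring and its count (state table) or
#' probability (distribution; zero-probability states are included).
#'
#' @param x a `qccc_state_table` or `qccc_probdist`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_states_tsv <- function(x, path) {
  if (inherits(x, "qccc_state_table")) {
    df <- data.frame(state = names(x$counts), count = as.integer(x$counts))
  } else if (inherits(x, "qccc_probdist")) {
    d <- round(log2(length(x)))
    df <- data.frame(state = index_to_bits(seq_along(x) - 1, d),
                     probability = as.numeric(x))
  } else {
    stop("x must be a qccc_state_table or qccc_probdist")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a topology to JSON
#'
#' An ordered array of `{control, target, angle_rad}` objects.
#'
#' @param tau a `qccc_topology`.
#' @param path output path; if `NULL`, the JSON string is returned instead.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_topology_json <- function(tau, path = NULL) {
  stopifnot(inherits(tau, "qccc_topology"))
  obj <- lapply(seq_len(nrow(tau)), function(i) {
    list(control = tau$control[i], target = tau$target[i],
         angle_rad = tau$angle[i])
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path JSON file written by [write_topology_json()].
#' @return a `qccc_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(obj) == 0) return(topology())
  topology(control = obj$control, target = obj$target, angle = obj$angle_rad)
}

#' Export a topology as OpenQASM 3
#'
#' @param tau a `qccc_topology`.
#' @param n_qubits register width of the circuit.
#' @param path output path; if `NULL`, the QASM text is returned.
#' @return `path` invisibly, or the QASM source as a character vector.
#' @export
write_openqasm <- function(tau, n_qubits, path = NULL) {
  stopifnot(inherits(tau, "qccc_topology"))
  lines <- c("OPENQASM 3.0;", "include \"stdgates.inc\";",
             sprintf("qubit[%d] q;", n_qubits))
  for (i in seq_len(nrow(tau))) {
    lines <- c(lines, sprintf("crx(%.17g) q[%d], q[%d];", tau$angle[i],
                              tau$control[i], tau$target[i]))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Materializes the output of [generate_rule_based()] as four Matrix Market
#' count matrices with features/barcodes annotations, four dense CSV
#' variants, two gene-selection lists, and the generating specification as
#' JSON.
#'
#' @param data output of [generate_rule_based()].
#' @param dir output directory (created if needed).
#' @return invisibly, the character vector of files written.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(data$counts)) {
    m <- data$counts[[nm]]
    mtx <- file.path(dir, paste0(nm, ".mtx"))
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), mtx)
    feats <- file.path(dir, paste0(nm, "_features.tsv"))
    writeLines(colnames(m), feats)
    bars <- file.path(dir, paste0(nm, "_barcodes.tsv"))
    writeLines(rownames(m), bars)
    csv <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(m), csv, row.names = TRUE)
    written <- c(written, mtx, feats, bars, csv)
  }
  g1 <- file.path(dir, "genes_ct1.txt")
  writeLines(data$ct1_genes, g1)
  g2 <- file.path(dir, "genes_ct2.txt")
  writeLines(data$ct2_genes, g2)
  spec_path <- file.path(dir, "truth_spec.json")
  spec <- data$spec
  jsonlite::write_json(
    list(ct1_genes = spec$ct1_genes, ct2_genes = spec$ct2_genes,
         baseline_on_prob = as.list(spec$baseline_on_prob),
         rules = spec$rules, n_cells = spec$n_cells, seed = spec$seed),
    spec_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(written, g1, g2, spec_path))
}

#' Read a ground-truth specification from JSON
#'
#' @param path JSON file as written by [write_synthetic_dataset()].
#' @return a `qccc_truth_spec`.
#' @export
read_truth_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  truth_spec(ct1_genes = obj$ct1_genes, ct2_genes = obj$ct2_genes,
             baseline_on_prob = unlist(obj$baseline_on_prob),
             rules = obj$rules, n_cells = obj$n_cells, seed = obj$seed)
}
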