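# Run configuration and the end-to-end pipeline driver: reads the four
# input populations and gene lists from disk, fits the model, and writes
# every stage artifact plus a manifest into a run directory.

#' Read a run configuration
#'
#' The configuration is a JSON (or YAML, if the yaml package is installed)
#' file with fields:
#' \preformatted{
#' inputs:
#'   ct1_mono: {dense: path}  or  {mtx: path, features: path, barcodes: path}
#'   ct1_co / ct2_mono / ct2_co: same shape
#'   genes_ct1: path   genes_ct2: path
#' encoding: {threshold: 0, target_total: null}
#' delta_cutoff: 0.01
#' search: {algorithm: multi_epoch, epochs: 10, max_gates: 10, ...}
#' refine: {optimizer: lbfgsb, enabled: true}
#' out_dir: path
#' seed: 1
#' }
#' Every referenced path must exist; validation errors name the offending
#' field.
#'
#' @param path configuration file.
#' @return validated configuration list of class `qccc_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  cfg$config_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- c("inputs", "out_dir")
  for (f in need) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  }
  resolve <- function(p) {
    if (file.exists(p)) return(p)
    p2 <- file.path(cfg$config_dir %||% ".", p)
    if (file.exists(p2)) return(p2)
    NA_character_
  }
  check_path <- function(p, field) {
    if (is.null(p)) stop("config field missing: ", field)
    r <- resolve(p)
    if (is.na(r)) stop("file not found for config field ", field, ": ", p)
    r
  }
  for (pop in c("ct1_mono", "ct1_co", "ct2_mono", "ct2_co")) {
    inp <- cfg$inputs[[pop]]
    if (is.null(inp)) stop("config field missing: inputs$", pop)
    if (!is.null(inp$dense)) {
      cfg$inputs[[pop]]$dense <- check_path(inp$dense,
                                            paste0("inputs$", pop, "$dense"))
    } else {
      for (f in c("mtx", "features", "barcodes")) {
        cfg$inputs[[pop]][[f]] <-
          check_path(inp[[f]], paste0("inputs$", pop, "$", f))
      }
    }
  }
  cfg$inputs$genes_ct1 <- check_path(cfg$inputs$genes_ct1, "inputs$genes_ct1")
  cfg$inputs$genes_ct2 <- check_path(cfg$inputs$genes_ct2, "inputs$genes_ct2")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$delta_cutoff <- as.numeric(cfg$delta_cutoff %||% 0.01)
  cfg$encoding <- cfg$encoding %||% list()
  cfg$search <- cfg$search %||% list()
  cfg$search$algorithm <- cfg$search$algorithm %||% "multi_epoch"
  cfg$refine <- cfg$refine %||% list()
  cfg$refine$optimizer <- cfg$refine$optimizer %||% "lbfgsb"
  cfg$refine$enabled <- isTRUE(cfg$refine$enabled %||% TRUE)
  structure(cfg, class = c("qccc_config", "list"))
}

load_population <- function(inp) {
  if (!is.null(inp$dense)) {
    read_counts_dense(inp$dense)
  } else {
    read_counts_mtx(inp$mtx, inp$features, inp$barcodes)
  }
}

#' Run the full inference pipeline from a configuration
#'
#' Executes encode, prune, search, refine and ablate in sequence and writes
#' the stage artifacts into the run directory: `topology.json` (refined
#' angles), `topology.qasm`, `candidates.tsv`, `ablation.tsv`,
#' `network.graphml`, `network_edges.tsv`, `trace.tsv` (search convergence),
#' and `manifest.json` (configuration echo, its MD5 hash, seed, package
#' version, and the headline KL values). Stage failures abort with the stage
#' name; artifacts already written are retained.
#'
#' @param config a `qccc_config`, or the path of a configuration file.
#' @param out_dir optional override of the configured output directory.
#' @return the fitted `qccc` model, invisibly; artifacts are on disk.
#' @export
run_qccc_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "qccc_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- stage("load", list(
    ct1_mono = load_population(config$inputs$ct1_mono),
    ct1_co = load_population(config$inputs$ct1_co),
    ct2_mono = load_population(config$inputs$ct2_mono),
    ct2_co = load_population(config$inputs$ct2_co),
    genes_ct1 = read_gene_list(config$inputs$genes_ct1),
    genes_ct2 = read_gene_list(config$inputs$genes_ct2)
  ))
  sc <- config$search
  sc$algorithm <- NULL
  fit <- stage("fit", qccc(
    ct1_mono = inputs$ct1_mono, ct1_co = inputs$ct1_co,
    ct2_mono = inputs$ct2_mono, ct2_co = inputs$ct2_co,
    genes_ct1 = inputs$genes_ct1, genes_ct2 = inputs$genes_ct2,
    threshold = as.numeric(config$encoding$threshold %||% 0),
    target_total = config$encoding$target_total,
    delta_cutoff = config$delta_cutoff,
    algorithm = config$search$algorithm,
    optimizer = config$refine$optimizer,
    refine_angles = config$refine$enabled,
    seed = config$seed, search_control = sc
  ))
  stage("write", {
    write_topology_json(fit$topology, file.path(out_dir, "topology.json"))
    write_openqasm(fit$topology, fit$n_ct1 + fit$n_ct2,
                   file.path(out_dir, "topology.qasm"))
    write_candidates_tsv(fit$candidates, file.path(out_dir, "candidates.tsv"),
                         gene_map = fit$gene_map)
    write_ablation_tsv(fit$ablation, file.path(out_dir, "ablation.tsv"))
    write_network(fit$network,
                  graphml_path = file.path(out_dir, "network.graphml"),
                  edgelist_path = file.path(out_dir, "network_edges.tsv"))
    utils::write.table(fit$search$trace, file.path(out_dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_echo <- unclass(config)
    cfg_json <- file.path(out_dir, "config_echo.json")
    jsonlite::write_json(cfg_echo, cfg_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", force = TRUE)
    manifest <- list(
      config_hash = unname(tools::md5sum(cfg_json)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("qccc")),
      algorithm = fit$algorithm,
      n_candidates = nrow(fit$candidates),
      n_gates = nrow(fit$topology),
      kl_baseline = fit$kl$baseline,
      kl_after_search = fit$kl$after_search,
      kl_final = fit$kl$final
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(fit)
}
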