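# End-to-end driver: ingest -> context -> signature -> score -> subnet
# (-> path). Stage outputs are materialised to disk so any stage can be
# re-run and inspected; the driver itself adds no computation.

.fmt_num <- function(x) sprintf("%.12g", x)

.write_weighted_tsv <- function(weighted, path) {
  out <- weighted
  out$log10_pscore <- .fmt_num(out$log10_pscore)
  out$confidence <- .fmt_num(out$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Configure a pipeline run
#'
#' Collects input paths and parameters for [run_pipeline()] and validates
#' them before any work is done. Defaults are the method's reference
#' settings: combined-score threshold 700 (strict), TPM threshold 1.0,
#' top-1-percent centric cutoff, maximum path length 8.
#'
#' @param drug_targets,ppi,regulatory Paths to the three interaction tables.
#' @param expression Character vector of one or more expression table paths.
#' @param signature Path to the `gene`/`z` signature table.
#' @param start_id Starting node identifier (required).
#' @param out_dir Output directory for stage artifacts and the run report.
#' @param end_id Optional endpoint for a best-path MoA query.
#' @param min_combined,tpm_threshold,max_fdr,max_len,fraction Stage
#'   parameters; `max_fdr = NULL` keeps every mapped signature gene as an
#'   endpoint.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A validated `moa_run_config` list.
#' @export
run_config <- function(drug_targets, ppi, regulatory, expression, signature,
                       start_id, out_dir, end_id = NULL, min_combined = 700,
                       tpm_threshold = 1.0, max_fdr = NULL, max_len = 8L,
                       fraction = 0.01, seed = 1L) {
  if (missing(start_id) || is.null(start_id) || !nzchar(start_id)) {
    stop("config error: start_id is required")
  }
  inputs <- c(drug_targets, ppi, regulatory, expression, signature)
  for (f in inputs) {
    if (!file.exists(f)) stop("config error: input file not found: ", f)
  }
  structure(list(drug_targets = drug_targets, ppi = ppi,
                 regulatory = regulatory, expression = expression,
                 signature = signature, start_id = start_id,
                 end_id = end_id, min_combined = min_combined,
                 tpm_threshold = tpm_threshold, max_fdr = max_fdr,
                 max_len = as.integer(max_len), fraction = fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "moa_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `moa_run_config`.
#' @export
read_run_config <- function(path) {
  conf <- yaml::read_yaml(path)
  do.call(run_config, conf)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full MoA pipeline
#'
#' Executes ingest, context filtering, signature scoring, path weighting and
#' centric-subnetwork extraction (plus a best-path query when `end_id` is
#' set), writing every stage output under `config$out_dir`: `network.tsv`,
#' `context_network.tsv`, `signature_scored.tsv`, `weighted_edges.tsv`,
#' `centric_subnetwork.tsv`/`.sif`, optionally `moa_path.json`, and a
#' `report.json` with stage counts, parameters and wall time. Floating-point
#' columns are written with 12 significant digits so identical inputs give
#' byte-identical outputs.
#'
#' @param config A `moa_run_config` from [run_config()].
#' @return Invisibly, the run report as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "moa_run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  network <- .stage("ingest", {
    dt <- read_interaction_table(config$drug_targets, "drug_target")
    ppi <- filter_ppi_records(read_interaction_table(config$ppi, "ppi"),
                              min_combined = config$min_combined)
    reg <- read_interaction_table(config$regulatory, "regulatory")
    build_reference_network(dt, ppi, reg)
  })
  write_network_tsv(network, file.path(config$out_dir, "network.tsv"))
  counts <- list(reference_nodes = nrow(network$nodes),
                 reference_edges = nrow(network$edges))

  context_net <- .stage("context", {
    tables <- lapply(config$expression, read_expression_table)
    filter_by_expression(network, tables, config$tpm_threshold)
  })
  write_network_tsv(context_net,
                    file.path(config$out_dir, "context_network.tsv"))
  counts$context_nodes <- nrow(context_net$nodes)
  counts$context_edges <- nrow(context_net$edges)

  sig <- .stage("signature", {
    sig <- compute_signature(read_signature_table(config$signature))
    sig <- map_signature(context_net, sig)
    if (!is.null(config$max_fdr)) {
      sig <- sig[sig$fdr <= config$max_fdr, , drop = FALSE]
    }
    sig
  })
  sig_out <- sig
  for (col in c("z", "p", "fdr")) sig_out[[col]] <- .fmt_num(sig_out[[col]])
  utils::write.table(sig_out,
                     file.path(config$out_dir, "signature_scored.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  counts$signature_endpoints <- nrow(sig)

  weighted <- .stage("score", {
    if (!config$start_id %in% context_net$nodes$node) {
      stop("start node '", config$start_id,
           "' is not in the context network")
    }
    score_perturbation(context_net, config$start_id, sig, config$max_len)
  })
  .write_weighted_tsv(weighted,
                      file.path(config$out_dir, "weighted_edges.tsv"))
  counts$scored_edges <- sum(weighted$confidence > 0)

  if (counts$scored_edges > 0) {
    subnet <- .stage("subnet",
                     extract_centric_subnetwork(weighted, config$fraction))
    .write_weighted_tsv(subnet$edges,
                        file.path(config$out_dir, "centric_subnetwork.tsv"))
    write_sif(subnet, file.path(config$out_dir, "centric_subnetwork.sif"))
    counts$centric_edges <- nrow(subnet$edges)
    counts$centric_cutoff_confidence <- subnet$cutoff_confidence
  } else {
    warning("no edge obtained positive confidence; centric subnetwork skipped")
    counts$centric_edges <- 0L
  }

  if (!is.null(config$end_id)) {
    path <- .stage("path",
                   best_moa_path(context_net, weighted, config$start_id,
                                 config$end_id, config$max_len))
    write_moa_path_json(path, file.path(config$out_dir, "moa_path.json"))
    counts$moa_path_length <- if (is.null(path$edges)) 0L else path$length
  }

  report <- list(
    parameters = unclass(config),
    counts = counts,
    version = as.character(utils::packageVersion("moanet")),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
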