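# Seeded synthetic fixtures: interaction tables, expression tables and a
# perturbation signature with a planted drug -> protein -> TF -> gene path,
# so every pipeline stage is testable without external databases.

#' Specify a synthetic fixture
#'
#' Describes a synthetic study: node counts per layer, Erdos-Renyi background
#' densities per edge type, the length of the planted mechanism path, the
#' fraction of genes that are differentially expressed, and the target BH-FDR
#' magnitude of those genes. The planted path runs drug -> target protein ->
#' (PPI chain) -> TF -> gene, with the final edge regulatory; the DE genes
#' are exactly the genes regulated by the planted TF, so they are the
#' perturbation's downstream readout. Background signature Z-scores are
#' standard normal; DE genes get `|Z|` solving to the requested FDR scale
#' after BH adjustment (`p_target = de_fdr_scale * n_de / n_genes`).
#'
#' @param n_drugs,n_proteins,n_tfs,n_genes Layer sizes. At least one TF is
#'   required (the planted path always ends in a regulatory edge).
#' @param ppi_density,regulatory_density Background edge probabilities in
#'   `(0, 1)`.
#' @param planted_path_length Planted path length in edges, at least 2
#'   (drug edge + optional PPI chain + regulatory edge); requires
#'   `n_proteins >= planted_path_length - 2`.
#' @param de_fraction Fraction of genes that are differentially expressed, in
#'   `[0, 1)`; 0 plants a path whose downstream gene shows no expression
#'   change.
#' @param de_fdr_scale Target FDR magnitude of DE genes, in `(0, 1)`.
#' @param seed Integer seed; identical specs and seeds give byte-identical
#'   fixture files.
#' @return A validated `moa_synthesis_spec` list.
#' @export
synthesis_spec <- function(n_drugs = 2, n_proteins = 10, n_tfs = 3,
                           n_genes = 40, ppi_density = 0.005,
                           regulatory_density = 0.005,
                           planted_path_length = 3, de_fraction = 0.5,
                           de_fdr_scale = 1e-6, seed = 1) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_proteins = as.integer(n_proteins),
               n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
               ppi_density = ppi_density,
               regulatory_density = regulatory_density,
               planted_path_length = as.integer(planted_path_length),
               de_fraction = de_fraction, de_fdr_scale = de_fdr_scale,
               seed = as.integer(seed))
  if (spec$n_drugs < 1 || spec$n_genes < 1 || spec$n_proteins < 0) {
    stop("node counts must be positive")
  }
  if (spec$planted_path_length < 2) {
    stop("planted_path_length must be at least 2")
  }
  if (spec$n_tfs < 1) {
    stop("at least one TF is required: the planted path ends in a regulatory edge")
  }
  if (spec$n_proteins < spec$planted_path_length - 2) {
    stop("n_proteins too small for the requested planted PPI chain")
  }
  for (d in c(spec$ppi_density, spec$regulatory_density)) {
    if (!is.numeric(d) || d <= 0 || d >= 1) {
      stop("densities must lie in (0, 1)")
    }
  }
  if (spec$de_fraction < 0 || spec$de_fraction >= 1) {
    stop("de_fraction must lie in [0, 1)")
  }
  if (spec$de_fdr_scale <= 0 || spec$de_fdr_scale >= 1) {
    stop("de_fdr_scale must lie in (0, 1)")
  }
  structure(spec, class = "moa_synthesis_spec")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
}

#' Generate a synthetic fixture on disk
#'
#' Writes the five pipeline input tables (drug targets, PPI, regulatory,
#' two expression datasets, signature) plus a JSON manifest recording the
#' spec, the planted path, the DE genes and row counts. All randomness comes
#' from `spec$seed`: the same spec produces byte-identical files.
#'
#' The PPI table deliberately contains some low-evidence rows (combined
#' score at or below 700, or zero experimental evidence) so the STRING-style
#' filter has work to do; both expression datasets mark a few background
#' nodes as lowly expressed so the context filter does too. Planted-path
#' nodes are always well expressed and planted PPI rows always pass the
#' evidence filter.
#'
#' @param spec A [synthesis_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`): file paths, the planted path, `start_id` (the planted
#'   drug target — the scoring start), the planted scored edges (the planted
#'   path minus the drug edge, which can never lie on a path from the
#'   start), DE genes, and per-file row counts.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "moa_synthesis_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  set.seed(spec$seed)
  drugs <- sprintf("DRUG%02d", seq_len(spec$n_drugs))
  prots <- if (spec$n_proteins > 0) {
    sprintf("PROT%02d", seq_len(spec$n_proteins))
  } else {
    character(0)
  }
  tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))

  # planted chain: drug, (L-2 proteins), TF, gene  -- L edges in total
  n_chain <- spec$planted_path_length - 2L
  planted_nodes <- c(drugs[1], if (n_chain > 0) prots[seq_len(n_chain)],
                     tfs[1], genes[1])
  planted_edges <- data.frame(
    source = planted_nodes[-length(planted_nodes)],
    target = planted_nodes[-1],
    edge_type = c("drug_target", rep("ppi", n_chain), "regulatory"),
    stringsAsFactors = FALSE)

  n_de <- as.integer(round(spec$de_fraction * spec$n_genes))
  de_genes <- if (n_de > 0) genes[seq_len(n_de)] else character(0)
  # the planted TF regulates the planted endpoint plus every DE gene
  planted_targets <- unique(c(genes[1], de_genes))

  # --- drug-target table --------------------------------------------------
  dt <- data.frame(drug = drugs[1], gene = planted_nodes[2],
                   stringsAsFactors = FALSE)
  pool <- c(prots, tfs)
  for (d in drugs[-1]) {
    k <- sample(1:2, 1)
    dt <- rbind(dt, data.frame(drug = d,
                               gene = sample(pool, min(k, length(pool))),
                               stringsAsFactors = FALSE))
  }

  # --- PPI table ----------------------------------------------------------
  planted_pairs <- character(0)
  ppi <- data.frame(protein1 = character(0), protein2 = character(0),
                    combined_score = integer(0), experimental = integer(0),
                    experimental_transferred = integer(0),
                    stringsAsFactors = FALSE)
  chain <- planted_nodes[2:(length(planted_nodes) - 1)]  # proteins + TF
  if (length(chain) > 1) {
    p1 <- chain[-length(chain)]
    p2 <- chain[-1]
    ppi <- rbind(ppi, data.frame(
      protein1 = p1, protein2 = p2,
      combined_score = sample(850:999, length(p1), replace = TRUE),
      experimental = sample(300:600, length(p1), replace = TRUE),
      experimental_transferred = sample(0:100, length(p1), replace = TRUE),
      stringsAsFactors = FALSE))
    planted_pairs <- paste(pmin(p1, p2), pmax(p1, p2), sep = "\r")
  }
  if (length(pool) > 1) {
    pairs <- utils::combn(pool, 2)
    key <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]),
                 sep = "\r")
    open <- !(key %in% planted_pairs)
    draw <- stats::runif(ncol(pairs))
    good <- open & draw < spec$ppi_density
    if (any(good)) {
      n <- sum(good)
      ppi <- rbind(ppi, data.frame(
        protein1 = pairs[1, good], protein2 = pairs[2, good],
        combined_score = sample(701:999, n, replace = TRUE),
        experimental = sample(1:600, n, replace = TRUE),
        experimental_transferred = sample(0:300, n, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    # low-evidence noise rows that the STRING-style filter must remove
    noise <- open & !good & draw < spec$ppi_density * 1.5
    if (any(noise)) {
      n <- sum(noise)
      fail_combined <- sample(c(TRUE, FALSE), n, replace = TRUE)
      ppi <- rbind(ppi, data.frame(
        protein1 = pairs[1, noise], protein2 = pairs[2, noise],
        combined_score = ifelse(fail_combined,
                                sample(100:700, n, replace = TRUE),
                                sample(701:999, n, replace = TRUE)),
        experimental = ifelse(fail_combined,
                              sample(0:600, n, replace = TRUE), 0L),
        experimental_transferred = 0L,
        stringsAsFactors = FALSE))
    }
  }

  # --- regulatory table ---------------------------------------------------
  reg <- data.frame(tf = tfs[1], gene = planted_targets,
                    stringsAsFactors = FALSE)
  grid_tf <- rep(tfs, each = spec$n_genes)
  grid_gene <- rep(genes, times = spec$n_tfs)
  hit <- stats::runif(length(grid_tf)) < spec$regulatory_density
  planted_key <- paste(reg$tf, reg$gene, sep = "\r")
  bg <- hit & !(paste(grid_tf, grid_gene, sep = "\r") %in% planted_key)
  if (any(bg)) {
    reg <- rbind(reg, data.frame(tf = grid_tf[bg], gene = grid_gene[bg],
                                 stringsAsFactors = FALSE))
  }

  # --- expression tables --------------------------------------------------
  expressed_nodes <- c(prots, tfs, genes)
  protected <- unique(c(planted_nodes[-1], de_genes))
  make_expression <- function() {
    tpm <- round(exp(stats::rnorm(length(expressed_nodes),
                                  mean = log(20), sd = 1)), 3)
    names(tpm) <- expressed_nodes
    tpm[protected] <- pmax(tpm[protected], 1.5)
    low_pool <- setdiff(expressed_nodes, protected)
    n_low <- max(1L, as.integer(round(0.05 * length(low_pool))))
    low <- sample(low_pool, min(n_low, length(low_pool)))
    tpm[low] <- round(stats::runif(length(low), 0, 0.9), 3)
    data.frame(gene = expressed_nodes, tpm = unname(tpm),
               stringsAsFactors = FALSE)
  }
  expr_a <- make_expression()
  expr_b <- make_expression()

  # --- signature ----------------------------------------------------------
  z <- stats::rnorm(spec$n_genes)
  if (n_de > 0) {
    p_target <- spec$de_fdr_scale * n_de / spec$n_genes
    z_mag <- stats::qnorm(p_target / 2, lower.tail = FALSE)
    z[seq_len(n_de)] <- z_mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  sig <- data.frame(gene = genes, z = round(z, 6), stringsAsFactors = FALSE)

  files <- list(
    drug_targets = file.path(out_dir, "drug_targets.tsv"),
    ppi = file.path(out_dir, "ppi.tsv"),
    regulatory = file.path(out_dir, "regulatory.tsv"),
    expression_a = file.path(out_dir, "expression_a.tsv"),
    expression_b = file.path(out_dir, "expression_b.tsv"),
    signature = file.path(out_dir, "signature.tsv"))
  .write_tsv(dt, files$drug_targets)
  .write_tsv(ppi, files$ppi)
  .write_tsv(reg, files$regulatory)
  .write_tsv(expr_a, files$expression_a)
  .write_tsv(expr_b, files$expression_b)
  .write_tsv(sig, files$signature)

  planted_scored <- planted_edges[planted_edges$edge_type != "drug_target", ,
                                  drop = FALSE]
  rownames(planted_scored) <- NULL
  manifest <- list(
    spec = unclass(spec),
    files = files,
    planted_nodes = planted_nodes,
    planted_edges = planted_edges,
    start_id = planted_nodes[2],
    planted_scored_edges = planted_scored,
    planted_endpoint = genes[1],
    de_genes = de_genes,
    counts = list(drug_target_rows = nrow(dt), ppi_rows = nrow(ppi),
                  regulatory_rows = nrow(reg),
                  expression_rows = nrow(expr_a),
                  signature_rows = nrow(sig)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.run_fixture_pipeline <- function(manifest, tpm_threshold = 1.0,
                                  min_combined = 700, max_fdr = 0.05,
                                  max_len = 8L) {
  files <- manifest$files
  dt <- read_interaction_table(files$drug_targets, "drug_target")
  ppi <- filter_ppi_records(read_interaction_table(files$ppi, "ppi"),
                            min_combined = min_combined)
  reg <- read_interaction_table(files$regulatory, "regulatory")
  network <- build_reference_network(dt, ppi, reg)
  network <- filter_by_expression(
    network, list(read_expression_table(files$expression_a),
                  read_expression_table(files$expression_b)),
    tpm_threshold)
  sig <- compute_signature(read_signature_table(files$signature))
  sig <- map_signature(network, sig)
  if (!is.null(max_fdr)) {
    sig <- sig[sig$fdr <= max_fdr, , drop = FALSE]
  }
  weighted <- score_perturbation(network, manifest$start_id, sig, max_len)
  list(network = network, signature = sig, weighted = weighted)
}

#' Planted-path recovery rate across seeded replicates
#'
#' For each replicate (seed `spec$seed + replicate - 1`) a fixture is
#' generated and the full pipeline is run with the planted drug target as
#' the starting node: ingest, STRING-style PPI filtering, context expression
#' filtering, signature scoring with an FDR endpoint cutoff, path weighting
#' and centric-subnetwork extraction. A replicate counts as recovered when
#' every planted scored edge (the planted path downstream of the start)
#' appears in the top-`fraction` centric subnetwork. Replicates in which no
#' edge obtains positive confidence count as not recovered.
#'
#' @param spec A [synthesis_spec()].
#' @param n_replicates Number of seeded replicates, at least 1.
#' @param fraction Centric-subnetwork fraction; default 0.05.
#' @param max_fdr Endpoint FDR cutoff applied to the mapped signature;
#'   default 0.05.
#' @param max_len Maximum constrained path length; default 8.
#' @return Recovery rate in `[0, 1]`.
#' @export
planted_path_recovery_rate <- function(spec, n_replicates, fraction = 0.05,
                                       max_fdr = 0.05, max_len = 8L) {
  stopifnot(inherits(spec, "moa_synthesis_spec"), n_replicates >= 1)
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    rspec <- spec
    rspec$seed <- spec$seed + (r - 1L)
    dir <- tempfile("moanet_fixture_")
    manifest <- generate_fixture(rspec, dir)
    res <- suppressMessages(suppressWarnings(
      .run_fixture_pipeline(manifest, max_fdr = max_fdr, max_len = max_len)))
    weighted <- res$weighted
    if (any(weighted$confidence > 0)) {
      subnet <- extract_centric_subnetwork(weighted, fraction)
      planted <- manifest$planted_scored_edges
      hits[r] <- all(.edge_key(planted) %in% .edge_key(subnet$edges))
    }
    unlink(dir, recursive = TRUE)
  }
  mean(hits)
}
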