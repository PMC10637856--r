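# Context-specific restriction of the reference network by expression.

#' Read a gene expression table
#'
#' Reads a two-column TSV (`gene`, `tpm`) into a named numeric vector of
#' transcripts-per-million values. Duplicate gene rows or negative TPM values
#' are errors.
#'
#' @param path Path to the TSV (header required).
#' @return Named numeric vector of TPM values.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("gene", "tpm"), names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed expression table '", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  gene <- as.character(tab$gene)
  tpm <- as.numeric(tab$tpm)
  if (anyDuplicated(gene)) {
    stop("duplicate gene identifiers in expression table: ", path)
  }
  if (any(is.na(tpm)) || any(tpm < 0)) {
    stop("TPM values must be non-negative numbers: ", path)
  }
  stats::setNames(tpm, gene)
}

.as_expression_vector <- function(tab) {
  if (is.data.frame(tab)) {
    tab <- stats::setNames(as.numeric(tab$tpm), as.character(tab$gene))
  }
  if (is.numeric(tab) && length(tab) == 0) {
    return(tab)  # caught by the empty-table check
  }
  if (!is.numeric(tab) || is.null(names(tab))) {
    stop("expression table must be a named numeric vector or a gene/tpm data frame")
  }
  tab
}

#' Restrict a network to a cell context by expression
#'
#' Removes every gene node that is lowly expressed in any of the supplied
#' expression datasets: a gene is dropped when its TPM is strictly below
#' `tpm_threshold` in at least one table, or when it is absent from a table
#' (absence is treated as TPM 0). A gene at exactly the threshold is kept.
#' Drug nodes are never removed. All edges incident to a removed node are
#' removed, and the TF set is intersected with the surviving nodes.
#'
#' @param network A `moa_network`.
#' @param tables One expression table or a list of them; each a named numeric
#'   TPM vector (see [read_expression_table()]) or a `gene`/`tpm` data frame.
#' @param tpm_threshold Positive expression threshold in TPM; default 1.0.
#' @return The filtered `moa_network`.
#' @export
filter_by_expression <- function(network, tables, tpm_threshold = 1.0) {
  stopifnot(inherits(network, "moa_network"))
  if (!is.numeric(tpm_threshold) || length(tpm_threshold) != 1 ||
      tpm_threshold <= 0) {
    stop("tpm_threshold must be a single positive number")
  }
  if (is.data.frame(tables) || !is.list(tables)) {
    tables <- list(tables)
  }
  if (length(tables) == 0) {
    stop("at least one expression table is required")
  }
  tables <- lapply(tables, .as_expression_vector)
  for (tab in tables) {
    if (length(tab) == 0) {
      stop("empty expression table: an empty filter would remove every gene")
    }
  }
  is_gene <- network$nodes$kind == "gene"
  genes <- network$nodes$node[is_gene]
  keep <- rep(TRUE, length(genes))
  for (tab in tables) {
    tpm <- unname(tab[genes])
    tpm[is.na(tpm)] <- 0
    keep <- keep & tpm >= tpm_threshold
  }
  if (any(!keep)) {
    message(sprintf("context filter: removed %d of %d gene nodes (TPM < %g)",
                    sum(!keep), length(genes), tpm_threshold))
  }
  keep_nodes <- c(network$nodes$node[!is_gene], genes[keep])
  edges <- network$edges
  edges <- edges[edges$source %in% keep_nodes & edges$target %in% keep_nodes, ,
                 drop = FALSE]
  nodes <- network$nodes[network$nodes$node %in% keep_nodes, , drop = FALSE]
  .new_moa_network(edges, nodes, intersect(network$tf_set, keep_nodes))
}
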