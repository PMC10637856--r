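# Reading the three interaction-source schemas and merging them into one
# directed, typed reference network.

.moanet_schemas <- list(
  drug_target = c("drug", "gene"),
  ppi         = c("protein1", "protein2", "combined_score", "experimental",
                  "experimental_transferred"),
  regulatory  = c("tf", "gene")
)

.edge_key <- function(edges) {
  paste(edges$source, edges$target, edges$edge_type, sep = "\r")
}

.empty_records <- function() {
  data.frame(source = character(), target = character(),
             edge_type = character(), combined_score = integer(),
             experimental = integer(), experimental_transferred = integer(),
             stringsAsFactors = FALSE)
}

#' Read an interaction source table
#'
#' Reads one of the three tab-separated interaction schemas (drug targets,
#' protein-protein interactions, or TF-gene regulatory interactions) into a
#' uniform record table. Rows with a missing source or target identifier are
#' rejected, and self-loop rows (source equal to target) are dropped; both
#' counts are reported via [message()].
#'
#' Expected headers: `drug`/`gene` for `drug_target`; `tf`/`gene` for
#' `regulatory`; `protein1`/`protein2`/`combined_score`/`experimental`/
#' `experimental_transferred` for `ppi`. Extra columns are ignored.
#'
#' @param path Path to a UTF-8 TSV file with a header row (LF or CRLF).
#' @param source_kind One of `"drug_target"`, `"ppi"`, `"regulatory"`.
#' @return A data frame of interaction records with columns `source`,
#'   `target`, `edge_type`, and (for PPI) the three STRING-style score
#'   columns; non-PPI records carry `NA` scores.
#' @seealso [filter_ppi_records()], [build_reference_network()]
#' @export
read_interaction_table <- function(path,
                                   source_kind = c("drug_target", "ppi",
                                                   "regulatory")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) {
    stop("interaction table not found: ", path)
  }
  cols <- .moanet_schemas[[source_kind]]
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0) {
    stop(sprintf("malformed %s table '%s': missing column(s): %s",
                 source_kind, path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    warning(sprintf("empty %s table: %s", source_kind, path))
    return(.empty_records())
  }
  src <- as.character(tab[[cols[1]]])
  tgt <- as.character(tab[[cols[2]]])
  rec <- data.frame(source = src, target = tgt, edge_type = source_kind,
                    combined_score = NA_integer_,
                    experimental = NA_integer_,
                    experimental_transferred = NA_integer_,
                    stringsAsFactors = FALSE)
  if (source_kind == "ppi") {
    rec$combined_score <- as.integer(tab[["combined_score"]])
    rec$experimental <- as.integer(tab[["experimental"]])
    rec$experimental_transferred <- as.integer(tab[["experimental_transferred"]])
  }
  bad <- is.na(rec$source) | rec$source == "" | is.na(rec$target) | rec$target == ""
  if (any(bad)) {
    message(sprintf("%s: rejected %d row(s) with missing identifiers",
                    source_kind, sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
  }
  loops <- rec$source == rec$target
  if (any(loops)) {
    message(sprintf("%s: dropped %d self-loop row(s)", source_kind, sum(loops)))
    rec <- rec[!loops, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Filter PPI records on STRING-style evidence scores
#'
#' Keeps a protein-protein interaction record only if its combined score is
#' strictly greater than `min_combined` and, when `require_experimental` is
#' set, at least one of the experimental or experimental-transferred evidence
#' scores is greater than zero. A record with a combined score exactly equal
#' to `min_combined` is excluded. Input order is preserved and the filter is
#' idempotent.
#'
#' @param records Data frame of interaction records, all with edge type
#'   `"ppi"` (see [read_interaction_table()]).
#' @param min_combined Minimum combined score (strict inequality); default
#'   700.
#' @param require_experimental Require experimental or
#'   experimental-transferred evidence greater than 0; default `TRUE`.
#' @return The filtered record data frame.
#' @export
filter_ppi_records <- function(records, min_combined = 700,
                               require_experimental = TRUE) {
  if (nrow(records) == 0) {
    return(records)
  }
  if (any(records$edge_type != "ppi")) {
    stop("filter_ppi_records expects records with edge_type 'ppi' only")
  }
  need <- c("combined_score", "experimental", "experimental_transferred")
  for (col in need) {
    if (any(is.na(records[[col]]))) {
      stop("PPI record with missing ", col, " cannot be filtered")
    }
  }
  keep <- records$combined_score > min_combined
  if (require_experimental) {
    keep <- keep & (records$experimental > 0 |
                      records$experimental_transferred > 0)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.new_moa_network <- function(edges, nodes, tf_set) {
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes, tf_set = tf_set),
            class = "moa_network")
}

#' Merge interaction records into a directed reference network
#'
#' Builds the typed, directed reference network from source-filtered record
#' tables. Drug-target and regulatory edges keep their source direction; each
#' PPI record is inserted in both directions. Duplicate
#' (source, target, edge_type) triples are collapsed. The transcription-factor
#' set is the set of source nodes of regulatory records, and a node is of kind
#' `"drug"` exactly when it appears as a drug-target source. An identifier
#' used both as a drug and as a regulatory source is an error: the drug and
#' gene namespaces share one identifier space and a collision is not silently
#' merged.
#'
#' @param drug_records,ppi_records,regulatory_records Record data frames from
#'   [read_interaction_table()] (PPI records already passed through
#'   [filter_ppi_records()]). Any of them may be `NULL` or empty.
#' @return A `moa_network` object: a list with `edges` (data frame `source`,
#'   `target`, `edge_type`), `nodes` (data frame `node`, `kind`), and
#'   `tf_set` (character vector).
#' @export
build_reference_network <- function(drug_records = NULL, ppi_records = NULL,
                                    regulatory_records = NULL) {
  take <- function(rec) {
    if (is.null(rec) || nrow(rec) == 0) {
      return(.empty_records()[, c("source", "target", "edge_type")])
    }
    rec[, c("source", "target", "edge_type"), drop = FALSE]
  }
  drug <- take(drug_records)
  ppi <- take(ppi_records)
  reg <- take(regulatory_records)
  if (nrow(ppi) > 0) {
    ppi <- rbind(ppi,
                 data.frame(source = ppi$target, target = ppi$source,
                            edge_type = "ppi", stringsAsFactors = FALSE))
  }
  edges <- rbind(drug, ppi, reg)
  edges <- edges[!duplicated(.edge_key(edges)), , drop = FALSE]

  drug_ids <- unique(drug$source)
  tf_set <- unique(reg$source)
  collision <- intersect(drug_ids, tf_set)
  if (length(collision) > 0) {
    stop("identifier collision across namespaces (drug and regulatory source): ",
         paste(collision, collapse = ", "))
  }
  all_ids <- unique(c(edges$source, edges$target))
  nodes <- data.frame(node = all_ids,
                      kind = ifelse(all_ids %in% drug_ids, "drug", "gene"),
                      stringsAsFactors = FALSE)
  .new_moa_network(edges, nodes, tf_set)
}

#' @export
print.moa_network <- function(x, ...) {
  tab <- table(factor(x$edges$edge_type,
                      levels = c("drug_target", "ppi", "regulatory")))
  cat("moa_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$kind == "drug"), "drugs ),", nrow(x$edges),
      "directed edges\n")
  cat("  drug_target:", tab[["drug_target"]], " ppi:", tab[["ppi"]],
      " regulatory:", tab[["regulatory"]], "\n")
  cat("  transcription factors:", length(x$tf_set), "\n")
  invisible(x)
}

#' Write a reference network as a typed edge list
#'
#' Writes the merged network as a three-column TSV (`source`, `target`,
#' `edge_type`). [read_network_tsv()] reconstructs an identical network from
#' this file: node kinds and the TF set are implied by edge types
#' (drug-target sources are drugs; regulatory sources are TFs).
#'
#' @param network A `moa_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a typed edge list back into a reference network
#'
#' @param path A TSV written by [write_network_tsv()] (columns `source`,
#'   `target`, `edge_type`).
#' @return A `moa_network`.
#' @export
read_network_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("source", "target", "edge_type")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed network table '", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ok_types <- c("drug_target", "ppi", "regulatory")
  if (!all(tab$edge_type %in% ok_types)) {
    stop("unknown edge_type in ", path)
  }
  split_rec <- function(kind) {
    sub <- tab[tab$edge_type == kind, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(source = sub$source, target = sub$target, edge_type = kind,
               stringsAsFactors = FALSE)
  }
  ppi <- split_rec("ppi")
  if (!is.null(ppi)) {
    # stored edges already hold both directions; keep one per unordered pair
    # so build_reference_network's mirroring restores the symmetric pair set
    a <- pmin(ppi$source, ppi$target)
    b <- pmax(ppi$source, ppi$target)
    ppi <- ppi[!duplicated(paste(a, b, sep = "\r")), , drop = FALSE]
  }
  build_reference_network(split_rec("drug_target"), ppi,
                          split_rec("regulatory"))
}
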