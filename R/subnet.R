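# Centric-subnetwork extraction and best-path MoA queries.

#' Extract the top-confidence centric subnetwork
#'
#' Ranks all edges with positive confidence in decreasing order, takes the
#' confidence at rank `ceiling(fraction * n)` as the cutoff, and returns
#' every edge with confidence at or above it — ties at the boundary are all
#' included, so the result may exceed the nominal count. Edges with
#' confidence 0 (never on a scored path) are not eligible.
#'
#' @param weighted Weighted edge data frame from [score_perturbation()].
#' @param fraction Top fraction of confidence scores to keep, in `(0, 1]`;
#'   default 0.01 (the top 1 percent).
#' @return A `moa_subnetwork`: list with `edges` (sorted by decreasing
#'   confidence, then source/target/type for reproducibility),
#'   `cutoff_confidence`, and `fraction`.
#' @export
extract_centric_subnetwork <- function(weighted, fraction = 0.01) {
  stopifnot(is.data.frame(weighted))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 ||
      fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  if (nrow(weighted) == 0) {
    stop("no weighted edges to extract a subnetwork from")
  }
  eligible <- weighted[weighted$confidence > 0, , drop = FALSE]
  if (nrow(eligible) == 0) {
    stop("no edges with positive confidence; nothing to extract")
  }
  ranked <- sort(eligible$confidence, decreasing = TRUE)
  cutoff <- ranked[ceiling(fraction * length(ranked))]
  out <- eligible[eligible$confidence >= cutoff, , drop = FALSE]
  out <- out[order(-out$confidence, out$source, out$target, out$edge_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(list(edges = out, cutoff_confidence = cutoff,
                 fraction = fraction),
            class = "moa_subnetwork")
}

#' @export
print.moa_subnetwork <- function(x, ...) {
  cat(sprintf(
    "moa_subnetwork: %d edge(s) at top %.4g%% (confidence cutoff %.6g)\n",
    nrow(x$edges), 100 * x$fraction, x$cutoff_confidence))
  invisible(x)
}

.path_node_seq <- function(edges) {
  c(edges$source, edges$target[nrow(edges)])
}

#' Highest-confidence MoA path between start and endpoint
#'
#' Among all constrained shortest paths from the start to the endpoint (same
#' path semantics as [constrained_shortest_paths()]), returns the path that
#' maximises the aggregate confidence, formalised as the sum over edges of
#' log10 confidence (equivalently the product of edge confidences, per the
#' edge-independence assumption). An edge with confidence 0 contributes
#' negative infinity, so paths containing unscored edges rank below any path
#' of all-positive confidences. Ties are broken deterministically by the
#' lexicographically smallest node-id sequence, then edge-type sequence.
#'
#' @param network A `moa_network`.
#' @param weighted Weighted edges for this perturbation
#'   ([score_perturbation()] with the same start).
#' @param start_id,endpoint_id Query nodes.
#' @param max_len Maximum constrained path length; default 8.
#' @return A `moa_path`: list with `edges` (edge data frame with a
#'   `confidence` column; `NULL` if no path), `length`,
#'   `log10_path_confidence`, and `status` (`"ok"` or an explanation).
#' @export
best_moa_path <- function(network, weighted, start_id, endpoint_id,
                          max_len = 8L) {
  action <- constrained_shortest_paths(network, start_id, endpoint_id,
                                       max_len)
  if (is.null(action)) {
    return(structure(list(edges = NULL, length = NA_integer_,
                          log10_path_confidence = NA_real_,
                          status = sprintf(
                            "no constrained path from %s to %s within %d steps",
                            start_id, endpoint_id, as.integer(max_len))),
                     class = "moa_path"))
  }
  conf <- stats::setNames(weighted$confidence, .edge_key(weighted))
  path_conf <- lapply(action$paths, function(p) {
    cf <- unname(conf[.edge_key(p)])
    cf[is.na(cf)] <- 0
    cf
  })
  scores <- vapply(path_conf, function(cf) sum(log10(cf)), numeric(1))
  node_seq <- vapply(action$paths,
                     function(p) paste(.path_node_seq(p), collapse = "\r"),
                     character(1))
  type_seq <- vapply(action$paths,
                     function(p) paste(p$edge_type, collapse = "\r"),
                     character(1))
  best <- order(-scores, node_seq, type_seq)[1]
  edges <- action$paths[[best]]
  edges$confidence <- path_conf[[best]]
  structure(list(edges = edges, length = nrow(edges),
                 log10_path_confidence = scores[best], status = "ok"),
            class = "moa_path")
}

#' @export
print.moa_path <- function(x, ...) {
  if (is.null(x$edges)) {
    cat("moa_path: empty (", x$status, ")\n")
    return(invisible(x))
  }
  cat(sprintf("moa_path: %s, %d edge(s), log10 path confidence %.6g\n",
              paste(.path_node_seq(x$edges), collapse = " -> "),
              x$length, x$log10_path_confidence))
  invisible(x)
}

#' Write a subnetwork (or any edge table) in SIF format
#'
#' @param x A `moa_subnetwork` or an edge data frame with `source`, `target`,
#'   `edge_type`.
#' @param path Output path; rows are `source<TAB>edge_type<TAB>target`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  edges <- if (inherits(x, "moa_subnetwork")) x$edges else x
  sif <- data.frame(source = edges$source, edge_type = edges$edge_type,
                    target = edges$target)
  utils::write.table(sif, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a subnetwork as GraphML for network viewers
#'
#' @param x A `moa_subnetwork` or a weighted edge data frame.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  edges <- if (inherits(x, "moa_subnetwork")) x$edges else x
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = unique(c(edges$source, edges$target)))
  igraph::E(g)$edge_type <- edges$edge_type
  if (!is.null(edges$confidence)) {
    igraph::E(g)$confidence <- edges$confidence
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialise an MoA path as JSON
#'
#' @param moa_path A `moa_path` from [best_moa_path()].
#' @param path Output JSON file listing ordered nodes, edge types, per-edge
#'   confidences and the aggregate log10 path confidence.
#' @return `path`, invisibly.
#' @export
write_moa_path_json <- function(moa_path, path) {
  stopifnot(inherits(moa_path, "moa_path"))
  payload <- if (is.null(moa_path$edges)) {
    list(status = moa_path$status)
  } else {
    list(status = moa_path$status,
         nodes = .path_node_seq(moa_path$edges),
         edge_types = moa_path$edges$edge_type,
         confidences = moa_path$edges$confidence,
         length = moa_path$length,
         log10_path_confidence = moa_path$log10_path_confidence)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
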