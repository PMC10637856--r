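# Core engine: constrained shortest-path enumeration and penalty-score
# accumulation.
#
# A "drug action" is the set of all minimum-length directed paths from the
# starting node to one endpoint whose final edge is a regulatory interaction
# leaving a transcription factor (expression changes are TF-mediated). Within
# an action of m shortest paths to an endpoint with BH-FDR f, every distinct
# edge on any of the paths receives penalty f^(1/m); an edge shared by
# several actions multiplies its penalties (independence assumption), and
# confidence = 1 - penalty. Penalties are accumulated in log10 space because
# thousands of actions drive products far below double-precision underflow.

.FDR_FLOOR <- 1e-300  # keeps log10(fdr) finite when BH returns exactly 0

#' Enumerate all constrained shortest paths for one endpoint
#'
#' Finds every minimum-length directed path from `start_id` to `endpoint_id`
#' whose final edge is a regulatory edge whose source is a transcription
#' factor. Minimality is over constrained paths only: a shorter unconstrained
#' route does not reduce the path length. The search runs in a view of the
#' graph in which the endpoint's incoming edges are restricted to regulatory
#' edges from TFs. Paths are simple, and parallel edges of different types
#' between the same node pair give rise to distinct paths (all counted in
#' `m`).
#'
#' @param network A `moa_network`.
#' @param start_id,endpoint_id Distinct node identifiers in the network.
#' @param max_len Maximum admissible path length in edges (default 8); if the
#'   constrained shortest length exceeds it the result is empty and the
#'   truncation is reported via [message()].
#' @return A `moa_action` object (fields `start_id`, `endpoint_id`, `paths` —
#'   a list of edge-sequence data frames —, `m`, `length`, `endpoint_fdr`,
#'   initially `NA`), or `NULL` when no constrained path of admissible length
#'   exists.
#' @export
constrained_shortest_paths <- function(network, start_id, endpoint_id,
                                       max_len = 8L) {
  stopifnot(inherits(network, "moa_network"))
  for (id in c(start_id, endpoint_id)) {
    if (!id %in% network$nodes$node) {
      stop("unknown node id: ", id)
    }
  }
  if (start_id == endpoint_id) {
    stop("start and endpoint must be distinct nodes")
  }
  ed <- network$edges
  allowed <- ed[ed$target != endpoint_id |
                  (ed$edge_type == "regulatory" &
                     ed$source %in% network$tf_set), , drop = FALSE]
  if (!any(allowed$target == endpoint_id)) {
    return(NULL)  # constraint unsatisfiable: no regulatory edge from a TF in
  }
  pairs <- unique(allowed[, c("source", "target")])
  g <- igraph::graph_from_data_frame(pairs, directed = TRUE,
                                     vertices = network$nodes$node)
  dist <- suppressWarnings(
    igraph::distances(g, v = start_id, to = endpoint_id, mode = "out")[1, 1])
  if (!is.finite(dist)) {
    return(NULL)
  }
  if (dist > max_len) {
    message(sprintf(
      "constrained shortest path %s -> %s has length %d > max_len %d; truncated",
      start_id, endpoint_id, as.integer(dist), as.integer(max_len)))
    return(NULL)
  }
  asp <- igraph::all_shortest_paths(g, from = start_id, to = endpoint_id,
                                    mode = "out")
  vpaths <- lapply(asp$res, igraph::as_ids)
  paths <- list()
  for (np in vpaths) {
    nhop <- length(np) - 1L
    hop_rows <- vector("list", nhop)
    for (i in seq_len(nhop)) {
      hop_rows[[i]] <- which(allowed$source == np[i] &
                               allowed$target == np[i + 1])
    }
    combos <- expand.grid(hop_rows, KEEP.OUT.ATTRS = FALSE)
    for (j in seq_len(nrow(combos))) {
      idx <- as.integer(unlist(combos[j, ], use.names = FALSE))
      seq_edges <- allowed[idx, c("source", "target", "edge_type"),
                           drop = FALSE]
      rownames(seq_edges) <- NULL
      paths[[length(paths) + 1L]] <- seq_edges
    }
  }
  structure(list(start_id = start_id, endpoint_id = endpoint_id,
                 paths = paths, m = length(paths),
                 length = as.integer(dist), endpoint_fdr = NA_real_),
            class = "moa_action")
}

#' @export
print.moa_action <- function(x, ...) {
  cat(sprintf("moa_action: %s -> %s, %d shortest path(s) of length %d, endpoint fdr %s\n",
              x$start_id, x$endpoint_id, x$m, x$length,
              format(x$endpoint_fdr)))
  invisible(x)
}

#' Assign per-action edge penalty scores
#'
#' Distributes the endpoint's FDR evenly across the action's `m` shortest
#' paths: every distinct edge in the union of the paths receives penalty
#' `fdr^(1/m)`, once per action regardless of how many of the m paths contain
#' it. Computed as `log10(fdr) / m` in log space; FDRs of exactly 0 are
#' floored at 1e-300 so log arithmetic stays finite.
#'
#' @param action A `moa_action` with `endpoint_fdr` set (in `(0, 1]`; zeros
#'   floored).
#' @return Data frame with one row per distinct edge: `source`, `target`,
#'   `edge_type`, `log10_pscore`, `pscore`.
#' @export
assign_action_pscores <- function(action) {
  stopifnot(inherits(action, "moa_action"))
  if (action$m < 1) {
    stop("action has no paths (m = 0)")
  }
  fdr <- action$endpoint_fdr
  if (!is.numeric(fdr) || length(fdr) != 1 || !is.finite(fdr) ||
      fdr < 0 || fdr > 1) {
    stop("endpoint_fdr must be a single value in [0, 1]")
  }
  fdr <- max(fdr, .FDR_FLOOR)
  all_edges <- do.call(rbind, action$paths)
  all_edges <- all_edges[!duplicated(.edge_key(all_edges)), , drop = FALSE]
  rownames(all_edges) <- NULL
  all_edges$log10_pscore <- log10(fdr) / action$m
  all_edges$pscore <- 10^all_edges$log10_pscore
  all_edges
}

#' Accumulate edge penalties across drug actions
#'
#' An edge involved in several actions (a common edge) multiplies the
#' per-action penalties it obtained; in log10 space its accumulated penalty
#' is the sum over actions of `log10(fdr_a) / m_a`. Every network edge
#' appears in the output; edges on no action keep `log10_pscore` 0 and
#' confidence 0. Confidence is `1 - 10^log10_pscore`, evaluated as
#' `-expm1(log10_pscore * log(10))` for precision. The result is independent
#' of action order.
#'
#' @param network A `moa_network`.
#' @param actions List of `moa_action` objects with `endpoint_fdr` set.
#' @return Data frame of weighted edges: `source`, `target`, `edge_type`,
#'   `log10_pscore`, `confidence`, `n_actions`.
#' @export
accumulate_edge_pscores <- function(network, actions) {
  stopifnot(inherits(network, "moa_network"))
  ed <- network$edges
  keys <- .edge_key(ed)
  lp <- stats::setNames(numeric(nrow(ed)), keys)
  n_act <- stats::setNames(integer(nrow(ed)), keys)
  for (action in actions) {
    scored <- assign_action_pscores(action)
    k <- .edge_key(scored)
    unknown <- setdiff(k, keys)
    if (length(unknown) > 0) {
      stop("action contains edges absent from the network")
    }
    lp[k] <- lp[k] + scored$log10_pscore
    n_act[k] <- n_act[k] + 1L
  }
  data.frame(source = ed$source, target = ed$target,
             edge_type = ed$edge_type,
             log10_pscore = unname(lp),
             confidence = -expm1(unname(lp) * log(10)),
             n_actions = unname(n_act),
             stringsAsFactors = FALSE)
}

#' Score every network edge against a perturbation
#'
#' Runs [constrained_shortest_paths()] from the starting node to each mapped
#' signature endpoint (one drug action per reachable endpoint), assigns the
#' per-action penalties ([assign_action_pscores()]) and accumulates them
#' across actions ([accumulate_edge_pscores()]). Endpoints equal to the start
#' node are skipped with a warning. The number of reachable endpoints and of
#' edges with positive confidence is reported via [message()].
#'
#' @param network A `moa_network`.
#' @param start_id Starting node (drug-binding target or modulated gene).
#' @param endpoints Scored, mapped signature data frame with columns `gene`
#'   and `fdr` (see [compute_signature()], [map_signature()]).
#' @param max_len Maximum constrained path length; default 8.
#' @return Weighted edge data frame as for [accumulate_edge_pscores()].
#' @export
score_perturbation <- function(network, start_id, endpoints, max_len = 8L) {
  stopifnot(inherits(network, "moa_network"))
  if (!start_id %in% network$nodes$node) {
    stop("unknown start node id: ", start_id)
  }
  stopifnot(is.data.frame(endpoints), all(c("gene", "fdr") %in% names(endpoints)))
  actions <- list()
  n_considered <- 0L
  for (i in seq_len(nrow(endpoints))) {
    gene <- endpoints$gene[i]
    if (gene == start_id) {
      warning("endpoint identical to the start node skipped: ", gene)
      next
    }
    n_considered <- n_considered + 1L
    action <- constrained_shortest_paths(network, start_id, gene, max_len)
    if (is.null(action)) next
    action$endpoint_fdr <- endpoints$fdr[i]
    actions[[length(actions) + 1L]] <- action
  }
  message(sprintf("scoring: %d of %d endpoints reachable from %s",
                  length(actions), n_considered, start_id))
  weighted <- accumulate_edge_pscores(network, actions)
  message(sprintf("scoring: %d edge(s) with confidence > 0",
                  sum(weighted$confidence > 0)))
  weighted
}
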