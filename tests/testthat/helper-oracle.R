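# Independent brute-force oracles. Nothing here calls the package's path
# machinery: paths are enumerated by depth-first search over edge rows,
# scores by explicit products without log arithmetic, and BH by the textbook
# step-up recipe.

# All simple directed paths start -> end of length <= max_len whose final
# edge is a regulatory edge leaving a TF, filtered to minimum length.
# Returns a list of edge data frames (source, target, edge_type).
oracle_constrained_shortest <- function(edges, tf_set, start, end,
                                        max_len = 8) {
  found <- list()
  recurse <- function(node, visited, idx_path) {
    if (length(idx_path) >= max_len) return(invisible(NULL))
    out <- which(edges$source == node)
    for (i in out) {
      tgt <- edges$target[i]
      if (tgt == end) {
        if (edges$edge_type[i] == "regulatory" && edges$source[i] %in% tf_set) {
          found[[length(found) + 1L]] <<- c(idx_path, i)
        }
      } else if (!(tgt %in% visited)) {
        recurse(tgt, c(visited, tgt), c(idx_path, i))
      }
    }
    invisible(NULL)
  }
  recurse(start, start, integer(0))
  if (length(found) == 0) return(list())
  lens <- vapply(found, length, integer(1))
  found <- found[lens == min(lens)]
  lapply(found, function(idx) {
    p <- edges[idx, c("source", "target", "edge_type"), drop = FALSE]
    rownames(p) <- NULL
    p
  })
}

# Canonical sorted string representation of a path set, for set equality.
canon_paths <- function(paths) {
  sort(vapply(paths, function(p) {
    paste(p$source, p$target, p$edge_type, sep = ":", collapse = "|")
  }, character(1)))
}

edge_key_of <- function(df) paste(df$source, df$target, df$edge_type, sep = "\r")

# Straight-line scoring: explicit fdr^(1/m) once per distinct edge per
# action, explicit products across actions, no log space.
oracle_score <- function(network, start, endpoints, max_len = 8) {
  pscore <- stats::setNames(rep(1, nrow(network$edges)),
                            edge_key_of(network$edges))
  n_act <- stats::setNames(rep(0L, nrow(network$edges)),
                           edge_key_of(network$edges))
  for (i in seq_len(nrow(endpoints))) {
    ep <- endpoints$gene[i]
    if (ep == start) next
    paths <- oracle_constrained_shortest(network$edges, network$tf_set,
                                         start, ep, max_len)
    if (length(paths) == 0) next
    m <- length(paths)
    fdr <- max(endpoints$fdr[i], 1e-300)
    union_edges <- unique(unlist(lapply(paths, edge_key_of)))
    pscore[union_edges] <- pscore[union_edges] * fdr^(1 / m)
    n_act[union_edges] <- n_act[union_edges] + 1L
  }
  data.frame(source = network$edges$source, target = network$edges$target,
             edge_type = network$edges$edge_type,
             confidence = unname(1 - pscore),
             n_actions = unname(n_act), stringsAsFactors = FALSE)
}

# Textbook BH step-up: sort ascending, p * n / rank, cumulative minimum from
# the largest rank down, cap at 1, restore input order.
oracle_bh <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Alternative formulation of the constrained search: shortest prefix to each
# TF regulator of the endpoint (in the graph with the endpoint removed),
# then append the regulatory edge. Used for the dual-route equivalence check.
alt_constrained_shortest <- function(network, start, end, max_len = 8) {
  ed <- network$edges
  last <- ed[ed$target == end & ed$edge_type == "regulatory" &
               ed$source %in% network$tf_set, , drop = FALSE]
  if (nrow(last) == 0) return(list())
  sub <- ed[ed$source != end & ed$target != end, , drop = FALSE]
  verts <- setdiff(network$nodes$node, end)
  g <- igraph::graph_from_data_frame(unique(sub[, c("source", "target")]),
                                     directed = TRUE, vertices = verts)
  regs <- unique(last$source)
  dists <- vapply(regs, function(t) {
    if (t == start) 0 else
      suppressWarnings(igraph::distances(g, v = start, to = t,
                                         mode = "out")[1, 1])
  }, numeric(1))
  if (all(!is.finite(dists))) return(list())
  best <- min(dists)
  if (best + 1 > max_len) return(list())
  out <- list()
  for (t in regs[dists == best]) {
    prefixes <- if (t == start) {
      list(start)  # single trivial prefix
    } else {
      lapply(igraph::all_shortest_paths(g, from = start, to = t,
                                        mode = "out")$res, igraph::as_ids)
    }
    last_t <- last[last$source == t, , drop = FALSE]
    for (np in prefixes) {
      for (pre in expand_node_path(sub, np)) {
        for (j in seq_len(nrow(last_t))) {
          p <- rbind(pre, last_t[j, c("source", "target", "edge_type")])
          rownames(p) <- NULL
          out[[length(out) + 1L]] <- p
        }
      }
    }
  }
  out
}

# Expand a node sequence into all parallel-typed edge sequences.
expand_node_path <- function(edges, np) {
  if (length(np) <= 1) {
    return(list(edges[0, c("source", "target", "edge_type"), drop = FALSE]))
  }
  hop_rows <- lapply(seq_len(length(np) - 1), function(i) {
    which(edges$source == np[i] & edges$target == np[i + 1])
  })
  combos <- expand.grid(hop_rows, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(j) {
    e <- edges[as.integer(unlist(combos[j, ], use.names = FALSE)),
               c("source", "target", "edge_type"), drop = FALSE]
    rownames(e) <- NULL
    e
  })
}

# Seeded random typed digraph with at most 12 nodes, built through the
# package's own constructor so all network invariants hold.
random_typed_network <- function(seed) {
  set.seed(seed)
  n_drug <- sample(0:2, 1)
  n_prot <- sample(2:4, 1)
  n_tf <- sample(1:3, 1)
  n_gene <- sample(2:3, 1)
  drugs <- sprintf("D%d", seq_len(n_drug))
  prots <- sprintf("P%d", seq_len(n_prot))
  tfs <- sprintf("T%d", seq_len(n_tf))
  genes <- sprintf("G%d", seq_len(n_gene))
  pool <- c(prots, tfs)

  drug_rec <- NULL
  if (n_drug > 0) {
    drug_rec <- do.call(rbind, lapply(seq_len(n_drug), function(i) {
      data.frame(source = drugs[i], target = sample(pool, sample(1:2, 1)),
                 edge_type = "drug_target", stringsAsFactors = FALSE)
    }))
    drug_rec$combined_score <- NA_integer_
    drug_rec$experimental <- NA_integer_
    drug_rec$experimental_transferred <- NA_integer_
  }

  pairs <- utils::combn(pool, 2)
  hit <- stats::runif(ncol(pairs)) < 0.35
  ppi_rec <- NULL
  if (any(hit)) {
    ppi_rec <- data.frame(source = pairs[1, hit], target = pairs[2, hit],
                          edge_type = "ppi",
                          combined_score = 800L, experimental = 100L,
                          experimental_transferred = 0L,
                          stringsAsFactors = FALSE)
  }

  # regulatory: TFs regulate genes, proteins and other TFs
  reg_targets <- c(pool, genes)
  grid <- expand.grid(tf = tfs, tgt = reg_targets, stringsAsFactors = FALSE)
  grid <- grid[grid$tf != grid$tgt, , drop = FALSE]
  hit <- stats::runif(nrow(grid)) < 0.3
  reg_rec <- NULL
  if (any(hit)) {
    reg_rec <- data.frame(source = grid$tf[hit], target = grid$tgt[hit],
                          edge_type = "regulatory",
                          combined_score = NA_integer_,
                          experimental = NA_integer_,
                          experimental_transferred = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  if (is.null(reg_rec)) {
    reg_rec <- data.frame(source = tfs[1], target = genes[1],
                          edge_type = "regulatory",
                          combined_score = NA_integer_,
                          experimental = NA_integer_,
                          experimental_transferred = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  build_reference_network(drug_rec, ppi_rec, reg_rec)
}

# A random perturbation over a random network: a start node and a scored
# endpoint table.
random_perturbation <- function(network, seed) {
  set.seed(seed + 10000)
  non_drug <- network$nodes$node[network$nodes$kind == "gene"]
  start <- sample(non_drug, 1)
  cand <- setdiff(network$nodes$node, start)
  eps <- sample(cand, min(length(cand), sample(2:5, 1)))
  list(start = start,
       endpoints = data.frame(gene = eps,
                              fdr = stats::runif(length(eps), 1e-8, 0.9),
                              stringsAsFactors = FALSE))
}

# Minimal record-table builder for hand-made fixtures.
rec <- function(source, target, edge_type, combined = NA_integer_,
                experimental = NA_integer_, transferred = NA_integer_) {
  data.frame(source = source, target = target, edge_type = edge_type,
             combined_score = as.integer(combined),
             experimental = as.integer(experimental),
             experimental_transferred = as.integer(transferred),
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}
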