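weighted_frame <- function(conf) {
  n <- length(conf)
  data.frame(source = sprintf("A%03d", seq_len(n)),
             target = sprintf("B%03d", seq_len(n)),
             edge_type = rep("ppi", n),
             log10_pscore = log10(1 - conf),
             confidence = conf,
             n_actions = as.integer(conf > 0),
             stringsAsFactors = FALSE)
}

test_that("centric cutoff is the ceil(fraction n) rank with boundary ties included", {
  set.seed(1)
  w <- weighted_frame(sample(seq(0.001, 0.999, length.out = 200)))
  sub <- extract_centric_subnetwork(w, 0.01)
  expect_equal(nrow(sub$edges), 2L)  # ceil(0.01 * 200), all distinct
  expect_equal(sub$cutoff_confidence, sort(w$confidence, TRUE)[2])
  expect_true(all(sub$edges$confidence >= sub$cutoff_confidence))

  w <- weighted_frame(c(0.9, 0.9, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2))
  sub <- extract_centric_subnetwork(w, 0.2)
  # rank-2 cutoff is 0.9; all three 0.9 edges come along
  expect_equal(sub$cutoff_confidence, 0.9)
  expect_equal(nrow(sub$edges), 3L)

  w <- weighted_frame(c(0.5, 0, 0.3, 0))
  sub <- extract_centric_subnetwork(w, 1.0)
  expect_equal(nrow(sub$edges), 2L)  # zero-confidence edges are ineligible

  expect_error(extract_centric_subnetwork(weighted_frame(numeric(0)), 0.01),
               "no weighted edges")
  expect_error(extract_centric_subnetwork(weighted_frame(c(0, 0)), 0.01),
               "positive confidence")
  expect_error(extract_centric_subnetwork(weighted_frame(0.5), 1.5),
               "\\(0, 1\\]")
})

test_that("subnetwork extraction is input-order invariant and nested in fraction", {
  set.seed(2)
  w <- weighted_frame(round(stats::runif(150), 3))
  sub <- extract_centric_subnetwork(w, 0.1)
  shuf <- extract_centric_subnetwork(w[sample(nrow(w)), ], 0.1)
  expect_equal(shuf$edges, sub$edges, ignore_attr = TRUE)

  fracs <- c(0.02, 0.05, 0.1, 0.5, 1.0)
  keys <- lapply(fracs, function(f) {
    edge_key_of(extract_centric_subnetwork(w, f)$edges)
  })
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
})

test_that("best path maximises the product of edge confidences", {
  # two length-2 routes S->A->E and S->B->E; A-route has the better product
  net <- build_reference_network(
    ppi_records = rbind(rec("S", "A", "ppi", 800, 1, 0),
                        rec("S", "B", "ppi", 800, 1, 0)),
    regulatory_records = rbind(rec("A", "E", "regulatory"),
                               rec("B", "E", "regulatory")))
  w <- data.frame(
    source = c("S", "S", "A", "B"), target = c("A", "B", "E", "E"),
    edge_type = c("ppi", "ppi", "regulatory", "regulatory"),
    confidence = c(0.9, 0.9, 0.9, 0.5))
  p <- best_moa_path(net, w, "S", "E")
  expect_equal(p$status, "ok")
  expect_equal(p$edges$target, c("A", "E"))
  expect_equal(p$log10_path_confidence, log10(0.9 * 0.9), tolerance = 1e-12)
  expect_equal(p$length, 2L)

  # equal products: lexicographically smallest node sequence wins
  w$confidence <- c(0.9, 0.9, 0.5, 0.5)
  p <- best_moa_path(net, w, "S", "E")
  expect_equal(p$edges$target, c("A", "E"))

  # a zero-confidence edge sends the A-route to -Inf despite lexicographic order
  w$confidence <- c(0.9, 0.9, 0, 0.5)
  p <- best_moa_path(net, w, "S", "E")
  expect_equal(p$edges$target, c("B", "E"))
  expect_true(is.finite(p$log10_path_confidence))

  # no constrained route: explanatory empty result
  p <- best_moa_path(net, w, "S", "A")
  expect_null(p$edges)
  expect_match(p$status, "no constrained path")
})

test_that("best path agrees with the brute-force argmax on random fixtures", {
  for (seed in 1:20) {
    net <- random_typed_network(seed)
    pert <- random_perturbation(net, seed)
    w <- suppressMessages(suppressWarnings(
      score_perturbation(net, pert$start, pert$endpoints)))
    conf <- stats::setNames(w$confidence, edge_key_of(w))
    for (ep in pert$endpoints$gene) {
      mine <- best_moa_path(net, w, pert$start, ep)
      ref_paths <- oracle_constrained_shortest(net$edges, net$tf_set,
                                               pert$start, ep)
      if (length(ref_paths) == 0) {
        expect_null(mine$edges)
        next
      }
      # the returned path must be one of the constrained shortest paths
      expect_true(paste(canon_paths(list(mine$edges[, 1:3])), collapse = "") %in%
                    canon_paths(ref_paths))
      scores <- vapply(ref_paths, function(p) {
        prod(unname(conf[edge_key_of(p)]))
      }, numeric(1))
      expect_equal(10^mine$log10_path_confidence, max(scores),
                   tolerance = 1e-9)
    }
  }
})

test_that("exports write SIF, GraphML and path JSON", {
  dir <- withr::local_tempdir()
  w <- weighted_frame(c(0.9, 0.7, 0.4))
  sub <- extract_centric_subnetwork(w, 1.0)
  sif <- readLines(write_sif(sub, file.path(dir, "sub.sif")))
  expect_equal(length(sif), nrow(sub$edges))
  expect_match(sif[1], "^A[0-9]+\tppi\tB[0-9]+$")
  gml <- readLines(write_graphml(sub, file.path(dir, "sub.graphml")),
                   warn = FALSE)
  expect_true(any(grepl("graphml", gml)))

  net <- build_reference_network(
    regulatory_records = rec("T", "G", "regulatory"))
  wp <- suppressMessages(score_perturbation(
    net, "T", data.frame(gene = "G", fdr = 0.04)))
  p <- best_moa_path(net, wp, "T", "G")
  js <- jsonlite::read_json(write_moa_path_json(p, file.path(dir, "p.json")))
  expect_equal(unlist(js$nodes), c("T", "G"))
  expect_equal(js$log10_path_confidence, log10(0.96), tolerance = 1e-9)
})
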