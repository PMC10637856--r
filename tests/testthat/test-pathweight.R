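# A small helper: build a moa_action by hand for penalty-arithmetic tests.
manual_action <- function(edges, m = 1L, fdr = NA_real_,
                          start = "S", end = "E") {
  structure(list(start_id = start, endpoint_id = end,
                 paths = if (is.data.frame(edges)) list(edges) else edges,
                 m = as.integer(m), length = NA_integer_,
                 endpoint_fdr = fdr),
            class = "moa_action")
}

test_that("direct TF regulation gives a single length-1 path; unsatisfiable constraints give NULL", {
  net <- build_reference_network(
    ppi_records = rec("A", "G", "ppi", 800, 1, 0),
    regulatory_records = rec("T", "G", "regulatory"))
  a <- constrained_shortest_paths(net, "T", "G")
  expect_s3_class(a, "moa_action")
  expect_equal(a$m, 1L)
  expect_equal(a$length, 1L)
  expect_equal(a$paths[[1]]$edge_type, "regulatory")

  # endpoint A has no incoming regulatory edge at all
  expect_null(constrained_shortest_paths(net, "T", "A"))
  expect_error(constrained_shortest_paths(net, "T", "NOPE"), "NOPE")
  expect_error(constrained_shortest_paths(net, "G", "G"), "distinct")
})

test_that("a shorter unconstrained route does not reduce the constrained length", {
  # S--E direct PPI (length 1, not admissible); S--T--E with regulatory last
  net <- build_reference_network(
    ppi_records = rbind(rec("S", "E", "ppi", 800, 1, 0),
                        rec("S", "T", "ppi", 800, 1, 0)),
    regulatory_records = rec("T", "E", "regulatory"))
  a <- constrained_shortest_paths(net, "S", "E")
  expect_equal(a$length, 2L)
  expect_equal(a$m, 1L)
  expect_equal(a$paths[[1]]$edge_type, c("ppi", "regulatory"))
})

test_that("parallel typed edges between one node pair yield distinct shortest paths", {
  # S -> T via both ppi and regulatory (S is itself a TF), then T -> G
  net <- build_reference_network(
    ppi_records = rec("S", "T", "ppi", 800, 1, 0),
    regulatory_records = rbind(rec("S", "T", "regulatory"),
                               rec("T", "G", "regulatory")))
  a <- constrained_shortest_paths(net, "S", "G")
  expect_equal(a$m, 2L)
  expect_setequal(vapply(a$paths, function(p) p$edge_type[1], character(1)),
                  c("ppi", "regulatory"))
})

test_that("max_len truncates with a message", {
  net <- build_reference_network(
    ppi_records = rbind(rec("S", "A", "ppi", 800, 1, 0),
                        rec("A", "T", "ppi", 800, 1, 0)),
    regulatory_records = rec("T", "G", "regulatory"))
  expect_message(out <- constrained_shortest_paths(net, "S", "G", max_len = 2L),
                 "truncated")
  expect_null(out)
  expect_equal(constrained_shortest_paths(net, "S", "G", max_len = 3L)$length,
               3L)
})

test_that("per-action penalties are the m-th root of the endpoint FDR, once per edge", {
  e1 <- data.frame(source = "S", target = "T", edge_type = "ppi")
  e2 <- data.frame(source = "T", target = "E", edge_type = "regulatory")
  p1 <- rbind(e1, e2)

  s <- assign_action_pscores(manual_action(p1, m = 1, fdr = 0.01))
  expect_equal(s$pscore, c(0.01, 0.01), tolerance = 1e-12)

  # two paths sharing edge e2: every distinct edge gets fdr^(1/2) once
  e3 <- data.frame(source = "S2", target = "E", edge_type = "regulatory")
  s <- assign_action_pscores(manual_action(list(p1, rbind(e1, e3)), m = 2,
                                           fdr = 0.04))
  expect_equal(nrow(s), 3L)
  expect_equal(s$pscore, rep(0.2, 3), tolerance = 1e-12)

  s <- assign_action_pscores(manual_action(p1, m = 3, fdr = 0.001))
  expect_equal(s$pscore, rep(0.1, 2), tolerance = 1e-12)
  expect_true(all(s$pscore >= 0.001))  # x^(1/m) >= x on (0, 1]

  expect_error(assign_action_pscores(manual_action(list(), m = 0, fdr = 0.1)),
               "m = 0")
  expect_error(assign_action_pscores(manual_action(p1, m = 1, fdr = 2)),
               "\\[0, 1\\]")
})

test_that("common edges multiply penalties across actions without underflow", {
  net <- build_reference_network(
    ppi_records = rec("S", "T", "ppi", 800, 1, 0),
    regulatory_records = rec("T", "E", "regulatory"))
  edge <- data.frame(source = "S", target = "T", edge_type = "ppi")

  two <- list(manual_action(edge, 1, 0.1), manual_action(edge, 1, 0.2))
  w <- accumulate_edge_pscores(net, two)
  hit <- w[w$source == "S" & w$target == "T", ]
  expect_equal(10^hit$log10_pscore, 0.02, tolerance = 1e-12)
  expect_equal(hit$confidence, 0.98, tolerance = 1e-12)
  expect_equal(hit$n_actions, 2L)
  # untouched edges stay at penalty 1 / confidence 0
  expect_equal(w$confidence[w$edge_type == "regulatory"], 0)
  expect_equal(w$log10_pscore[w$edge_type == "regulatory"], 0)

  one <- accumulate_edge_pscores(net, two[1])
  expect_equal(10^one$log10_pscore[one$source == "S" & one$target == "T"],
               0.1, tolerance = 1e-12)

  # 1000 actions at 0.5 each: product underflows doubles, the log field must not
  many <- replicate(1000, manual_action(edge, 1, 0.5), simplify = FALSE)
  w <- accumulate_edge_pscores(net, many)
  hit <- w[w$source == "S" & w$target == "T", ]
  expect_equal(hit$log10_pscore, 1000 * log10(0.5), tolerance = 1e-9)
  expect_true(is.finite(hit$log10_pscore))

  # confidence identity 1 - 10^log10_pscore holds everywhere
  expect_equal(w$confidence, -expm1(w$log10_pscore * log(10)),
               tolerance = 1e-12)
})

test_that("scoring matches a brute-force oracle on random typed digraphs", {
  for (seed in 1:30) {
    net <- random_typed_network(seed)
    pert <- random_perturbation(net, seed)
    for (ep in pert$endpoints$gene) {
      mine <- constrained_shortest_paths(net, pert$start, ep)
      ref <- oracle_constrained_shortest(net$edges, net$tf_set,
                                         pert$start, ep)
      if (is.null(mine)) {
        expect_length(ref, 0)
      } else {
        expect_equal(canon_paths(mine$paths), canon_paths(ref))
      }
    }
    mine <- suppressMessages(suppressWarnings(
      score_perturbation(net, pert$start, pert$endpoints)))
    ref <- oracle_score(net, pert$start, pert$endpoints)
    expect_equal(mine$confidence, ref$confidence, tolerance = 1e-9)
    expect_equal(mine$n_actions, ref$n_actions)
  }
})

test_that("restricted-view search equals the search-to-TF-then-append formulation", {
  for (seed in 1:25) {
    net <- random_typed_network(seed)
    pert <- random_perturbation(net, seed)
    for (ep in pert$endpoints$gene) {
      mine <- constrained_shortest_paths(net, pert$start, ep)
      alt <- alt_constrained_shortest(net, pert$start, ep)
      if (is.null(mine)) {
        expect_length(alt, 0)
      } else {
        expect_equal(canon_paths(mine$paths), canon_paths(alt))
      }
    }
  }
})

test_that("edge confidences are action-order invariant and monotone in added actions", {
  for (seed in 1:10) {
    net <- random_typed_network(seed)
    pert <- random_perturbation(net, seed)
    base <- suppressMessages(suppressWarnings(
      score_perturbation(net, pert$start, pert$endpoints)))
    set.seed(seed)
    shuffled <- pert$endpoints[sample(nrow(pert$endpoints)), , drop = FALSE]
    again <- suppressMessages(suppressWarnings(
      score_perturbation(net, pert$start, shuffled)))
    expect_equal(again, base, tolerance = 1e-12)

    # dropping the last endpoint can only lower (or keep) confidences
    fewer <- suppressMessages(suppressWarnings(score_perturbation(
      net, pert$start,
      pert$endpoints[-nrow(pert$endpoints), , drop = FALSE])))
    expect_true(all(base$confidence - fewer$confidence >= -1e-12))
    expect_true(all(base$confidence >= 0 & base$confidence < 1))
  }
})

test_that("endpoints equal to the start are skipped with a warning", {
  net <- build_reference_network(
    regulatory_records = rec("T", "G", "regulatory"))
  eps <- data.frame(gene = c("T", "G"), fdr = c(0.5, 0.09))
  expect_warning(w <- suppressMessages(score_perturbation(net, "T", eps)),
                 "identical to the start")
  expect_equal(w$confidence[w$source == "T" & w$target == "G"], 0.91,
               tolerance = 1e-12)
  expect_error(suppressMessages(score_perturbation(net, "ZZ", eps)), "ZZ")
})
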