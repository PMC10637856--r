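# moanet

Mechanism-of-action (MoA) subnetwork inference from typed multi-omics
interaction networks.

## What problem this solves

A repurposed drug binds a known protein, and a perturbation experiment
shows which genes change expression afterwards — but the step-by-step
molecular chain between the binding site and those transcriptional changes
is a black box. `moanet` is for computational biologists who have (i) a
typed interaction network — drug→target edges, protein–protein
interactions (PPIs), and TF→gene regulatory edges —, (ii) expression data
defining a cell context, and (iii) a perturbation signature of Z-scores,
and who want the most probable mechanism connecting a starting node to its
downstream effects.

## The model

The three interaction layers are merged into one directed network (PPIs
bidirectional, STRING-style evidence filter: combined score > 700 and
experimental evidence > 0), then restricted to a cell context by removing
genes with TPM < 1 in any expression dataset. Signature Z-scores become
two-tailed normal p-values, `p = 2(1 − Φ(|z|))`, and BH false discovery
rates; an endpoint's FDR is its *penalty score* — the probability its
expression did not change.

For each endpoint, all constrained shortest paths from the start are
enumerated, where the final edge of every path must be a regulatory edge
leaving a transcription factor (expression changes are TF-mediated). If an
endpoint with FDR *f* is reached by *m* shortest paths (one *drug
action*), every distinct edge on those paths receives

```
PScore(se) = f^(1/m)
```

once per action; an edge involved in several actions multiplies its
penalties, `PScore(ce) = Π PScore(se_i)` (edge independence), and

```
Confidence = 1 − PScore
```

Accumulation is done in log10 space so products over thousands of actions
cannot underflow. The top fraction (default 1%) of positive confidences
forms the *centric subnetwork*; the highest-confidence constrained
shortest path (maximum product of edge confidences) answers step-by-step
MoA queries.

## Worked example

Everything runs on seeded synthetic data with a planted
drug→protein→TF→gene mechanism — no external databases needed:

```r
library(moanet)

spec <- synthesis_spec(n_drugs = 2, n_proteins = 10, n_tfs = 3, n_genes = 40,
                       ppi_density = 0.005, regulatory_density = 0.005,
                       planted_path_length = 3, de_fraction = 0.5,
                       de_fdr_scale = 1e-6, seed = 1)
fixtures <- generate_fixture(spec, "demo")
fixtures$planted_nodes
#> [1] "DRUG01"  "PROT01"  "TF01"    "GENE001"

net <- build_reference_network(
  read_interaction_table(fixtures$files$drug_targets, "drug_target"),
  filter_ppi_records(read_interaction_table(fixtures$files$ppi, "ppi")),
  read_interaction_table(fixtures$files$regulatory, "regulatory"))
net
#> moa_network: 25 nodes ( 2 drugs ), 24 directed edges
#>   drug_target: 2  ppi: 2  regulatory: 20
#>   transcription factors: 1

net <- filter_by_expression(net,
  list(read_expression_table(fixtures$files$expression_a),
       read_expression_table(fixtures$files$expression_b)))
sig <- map_signature(net,
  compute_signature(read_signature_table(fixtures$files$signature)))
#> signature mapping: 20 mapped / 20 unmapped
head(sig, 3)
#>      gene         z            p          fdr
#> 1 GENE001 -5.026313 4.999996e-07 9.999991e-07
#> 2 GENE002  5.026313 4.999996e-07 9.999991e-07
#> 3 GENE003 -5.026313 4.999996e-07 9.999991e-07

weighted <- score_perturbation(net, "PROT01", sig[sig$fdr <= 0.05, ])
#> scoring: 20 of 20 endpoints reachable from PROT01
#> scoring: 21 edge(s) with confidence > 0
head(weighted[order(-weighted$confidence), ], 4)
#>   source  target  edge_type log10_pscore confidence n_actions
#> 3 PROT01    TF01        ppi         -120   1.000000        20
#> 5   TF01 GENE001 regulatory           -6   0.999999         1
#> 6   TF01 GENE002 regulatory           -6   0.999999         1
#> 7   TF01 GENE003 regulatory           -6   0.999999         1

extract_centric_subnetwork(weighted, fraction = 0.05)
#> moa_subnetwork: 21 edge(s) at top 5% (confidence cutoff 0.999999)

best_moa_path(net, weighted, "PROT01", "GENE001")
#> moa_path: PROT01 -> TF01 -> GENE001, 2 edge(s), log10 path confidence -4.34294e-07
```

Reading the numbers: the PPI edge `PROT01→TF01` is common to all 20 drug
actions, so its accumulated log10 penalty is 20 × (−6) = −120 and its
confidence is indistinguishable from 1; each regulatory edge serves a
single endpoint at FDR 1e−6 (penalty 10⁻⁶, confidence 0.999999). The
planted mechanism is exactly the returned best path.

`run_pipeline(run_config(...))` chains the same stages, materialises every
intermediate table plus a JSON run report, and
`inst/cli/moanet.R` exposes each stage as a shell subcommand
(`build`, `context`, `signature`, `score`, `subnet`, `path`, `synth`,
`run`).

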