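---
title: "Inferring mechanisms of action from typed interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mechanisms of action from typed interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

## The problem

A drug (or an siRNA) binds a protein, and days later hundreds of genes have
changed expression. The step-by-step molecular chain connecting the binding
site to those transcriptional changes — the mechanism of action (MoA) — is
usually unknown, especially for repurposed compounds. `moanet` infers it
from three layers of interaction evidence merged into one directed, typed
network: drug→target edges, protein–protein interactions (PPIs, stored
bidirectionally), and TF→gene regulatory edges. Given a starting node and a
perturbation signature, it scores every edge by how likely it is to lie on
an active mechanism path, and extracts the top-scoring ("centric")
subnetwork or the single most probable path.

## The model

Three assumptions underpin the scoring:

1. the merged network is treated as the universe of possible interactions;
2. edges are independent biological events, so probabilities multiply;
3. a perturbed gene is most plausibly reached through a *shortest* path,
   and, because expression changes are mediated by transcription factors,
   the **final edge of every path must be a regulatory edge leaving a TF**.

Each signature gene (an *endpoint*) carries a penalty score: its BH false
discovery rate, i.e. a probability-like weight that its expression did
*not* change. Z-scores are converted to two-tailed normal p-values,
`p = 2(1 − Φ(|z|))`, and BH-adjusted **on the full signature before any
mapping onto the network** — adjusting after subsetting would inflate
significance and is a known pitfall.

For one endpoint with FDR `f`, let `m` be the number of constrained
shortest paths from the start (a *drug action*). If the endpoint really was
perturbed, at least one of the `m` routes was active, so the penalty is
distributed evenly: every **distinct** edge on any of the `m` paths
receives

    PScore(se) = f^(1/m)

once per action, regardless of how many of the `m` paths contain it. An
edge shared by several actions (a *common edge*) multiplies the penalties
it collected,

    PScore(ce) = PScore(se1) × PScore(se2) × … × PScore(sen),

and each edge's confidence is

    Confidence = 1 − PScore.

Edges on no action keep penalty 1 and confidence 0. With thousands of
endpoints the products underflow double precision long before they stop
being informative, so all accumulation is done in log10 space
(`log10 f / m` summed per edge) and confidence is evaluated as
`-expm1(log10P · ln 10)`; the stored log-penalty stays finite even when the
printed confidence rounds to 1.

## Path semantics and numerical choices

*Constrained shortest paths.* Paths are simple, directed, and counted as
edge sequences: parallel edges of different types between the same node
pair are distinct edges, so a node sequence traversing such a pair yields
one path per parallel edge, all counted in `m`. Minimality is over
*constrained* paths only — a shorter route whose last edge is not
TF-regulatory does not reduce the admissible length. The search runs in a
view of the graph in which the endpoint's incoming edges are restricted to
regulatory edges from TFs; the equivalent formulation (shortest path to
each TF regulator, then append the regulatory edge) is checked against it
in the test suite on random graphs.

*Aggregate path score.* For best-path queries the "highest confidence"
path is formalised as the maximum product of edge confidences (sum of
log10 confidences), consistent with the edge-independence assumption. The
model itself never defines the aggregate; minimum-edge or mean-edge
aggregation are defensible alternatives but are not implemented. Ties are
broken by the lexicographically smallest node-id sequence, then edge-type
sequence — needed because parallel typed edges can produce equal-score
paths over identical node sequences. An edge with confidence 0 contributes
−∞, so any path of all-positive confidences outranks one that leaves the
scored subnetwork.

*Centric subnetwork.* Among edges with positive confidence sorted
decreasingly, the cutoff is the confidence at rank `⌈fraction · n⌉` and
every edge at or above it is kept, so boundary ties may push the output
slightly past the nominal count. The reference analyses this package
models also report slightly-off-nominal edge counts, which is consistent
with tie tolerance.

*Degenerate inputs.* FDRs of exactly 0 are floored at 1e−300 before taking
logs. Endpoints identical to the start are skipped with a warning.
Self-loops are dropped at read time; they can never sit on a shortest
path. An identifier appearing both as a drug and as a regulatory source is
an error rather than a silent merge — the two namespaces share one
identifier space and a collision is almost certainly an upstream data
problem. Identifiers are matched verbatim (no case folding): gene-symbol
case conventions are species-significant.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_combined` | 700 | STRING-style combined-score threshold, strict `>`; a PPI at exactly 700 is excluded |
| `require_experimental` | `TRUE` | keep a PPI only if experimental or experimental-transferred evidence > 0 |
| `tpm_threshold` | 1.0 TPM | context filter; a gene strictly below it **in any** expression dataset is removed, and absence from a dataset counts as 0 |
| `max_fdr` | `NULL` | optional endpoint cutoff; by default every mapped signature gene is an endpoint, since high-FDR endpoints already contribute near-unit penalties |
| `max_len` | 8 edges | cap on constrained path length; all-shortest-path enumeration on dense graphs can blow up combinatorially, truncation is reported |
| `fraction` | 0.01 | centric-subnetwork fraction (top 1% of confidences) |

The defaults reproduce the reference settings (700, 1.0, top 1%). Drug
nodes bypass the expression filter: the filter is about gene expression,
and drugs are not genes. Treating absence-from-a-dataset as TPM 0 is a
deliberate choice — the reference HepG2 analysis keeps genes passing *both*
of two datasets, implying absence means low.

## The synthetic generator

Real runs of this method depend on specific releases of large interaction
and expression resources. The packaged generator instead emulates their
schemas at desk scale so every stage is testable offline. It plants a
known mechanism — `drug → target protein → (PPI chain) → TF → gene` — in
an Erdős–Rényi background per edge type (the simplest null that still
produces multi-path `m > 1` cases), writes the five input tables plus a
JSON manifest, and is byte-reproducible from its seed. Differentially
expressed genes are exactly the planted TF's targets; their `|Z|` solves
to a requested BH-FDR magnitude (`p_target = de_fdr_scale · n_de / n`).
Low-evidence PPI rows and lowly-expressed background nodes are included on
purpose so the filters are exercised end to end.

Recovery is measured from the planted drug *target* (scoring starts at the
binding site, so the drug→target edge itself can never lie on a scored
path): a replicate is recovered when every planted edge downstream of the
start lands in the top-fraction centric subnetwork. The noise-free
validation design used by the tests and the acceptance script — 2 drugs,
10 proteins, 3 TFs, 40 genes, densities 0.005, planted length 3, half the
genes DE at FDR ≈ 1e−6, top-5% cutoff over 20 replicates — was chosen so
that the single planted chain edge (common to ~20 actions) and the ~20
planted regulatory edges are the only confidently scored edges, with the
rank boundary falling below the regulatory tier. What the generator does
*not* emulate: scale-free topology, CMap moderated-Z statistics,
identifier mapping, or literature bias — passing these tests shows the
arithmetic and path semantics are right, not that real networks are this
clean.

## What the tests check

Formula exactness on hand-computable cases (`f = 0.04, m = 2 → 0.2`;
`0.1 × 0.2 → 0.02 → confidence 0.98`) to 1e−12; exact path-set and 1e−9
score agreement with a brute-force depth-first enumerator on 100 seeded
random typed digraphs of at most 12 nodes; normal-tail p-values against
the closed-form `erfc` oracle to 1e−10 over `z ∈ [−8, 8]` and BH against
the textbook step-up on 1000 random vectors; strict boundary behaviour of
both filters; randomized invariants (action-order invariance, confidence
monotonicity under added actions, fraction nesting, PPI symmetry); and
100% planted-path recovery over 20 noise-free replicates, with zero scored
edges when no gene is differentially expressed. These problem sizes keep
the full suite under half a minute while covering every code path.

## Limitations

Confidence measures probability of involvement, not effect size: a
suboptimal-confidence path can still carry most of the biological effect.
The method cannot see mechanisms outside the supplied network (metabolic
or miRNA regulation, unannotated interactions), inherits any literature
bias of its sources, and rests on the shortest-path heuristic — real
signalling sometimes takes longer routes. Weighted (non-topological)
shortest paths, stochastic path sampling, and diffusion-style alternatives
are out of scope.
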