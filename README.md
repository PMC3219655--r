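# ocmirnet

miRNA-centred regulatory network analysis for ovarian cancer (OC), packaged
as a reusable pipeline. `ocmirnet` builds heterogeneous networks that couple
three layers of molecular interactions, ranks every node by a stochastic
edge-weight influence score, enumerates the regulatory loop motifs that can
act as feedback circuits, and compares pathway membership of loop-involved
genes against the disease-gene background.

## Who this is for

Systems-biology analyses of miRNA regulation typically start from the same
five kinds of association tables:

1. experimentally verified miRNA → target pairs (TarBase/miRTarBase-style),
2. a curated disease gene list (DDOC-style),
3. transcription-factor binding-site (TFBS) hits in miRNA promoter windows,
   scored by core and matrix scores (TRANSFAC-style scans of 1000nt and
   5000nt upstream regions),
4. TF–transcription-co-factor (TcoF) interaction pairs with a confidence
   label (TcoF-DB-style),
5. protein–protein interactions (PPI).

`ocmirnet` consumes such tables (headered TSV, with column mappings for
third-party layouts), applies the retention cascade — miRNAs with at least
one disease-associated verified target; their targets; TFs with at least one
high-scoring binding-site hit (core and matrix score ≥ 0.9) in a retained
miRNA promoter; high-confidence TcoFs of retained TFs; PPIs induced on the
retained proteins only — and produces one network per promoter window
(NW1000, NW5000).

## The model

The network is a weighted directed graph with three edge types:
miRNA → target (weight `e_t`, directed), TF → miRNA (`e_r`, directed) and
PPI (`e_i`, undirected, counted as outgoing from both endpoints). The
influence score of node *n* is

```
S_n = Σ e_n1 + w · Σ e_n2
```

where `e_n1` are the weights of *n*'s outgoing edges, `e_n2` the weights of
the outgoing edges of *n*'s distinct first-degree out-neighbours, and
`w ∈ (0,1)` damps the second degree. No canonical weighting exists, only the
hierarchy `1 = e_t > e_r > e_i > 0`, so each repetition draws
`e_r ~ U(0,1)`, `e_i ~ U(0, e_r)` and `w ~ U(0,1)`, scores and ranks all
nodes (fractional ranks for ties), and the final statistic is each node's
average rank over 10,000 repetitions.

Two motif families are enumerated: *self-loops* (a miRNA targeting one of
its own predicted TFs) and *three-element feedback loops*
(TF → miRNA → target, closed by a PPI between target and TF, target
disease-associated). Enrichment of loop targets in a pathway is tested with
the exact one-sided hypergeometric tail.

A synthetic-data generator (`generator_config()` / `generate_tables()`)
emits all five tables with nested promoter windows, score distributions
straddling the 0.9 filter threshold, role overlaps, planted motifs and a
ground-truth ledger, so the full pipeline is testable without any database
downloads. `published_scale_config()` reproduces the published networks' scale
(162 miRNAs, 131 targets, 244 TFs, 140 TcoFs, ~10,000/~19,600 edges).

## Worked example

```r
library(ocmirnet)

gen <- generate_tables(generator_config(seed = 42,
                                        n_planted_feedback_loops = 2))
net <- build_from_tables(gen, promoter_window = 1000)
print(net)
#> <ocm_network> promoter window: 1000 nt
#>   49 nodes (20 miRNAs, 15 targets, 10 TFs, 5 TcoFs)
#>   88 edges (34 targeting, 31 regulation, 23 PPI)

head(rank_nodes(net, repetitions = 200, seed = 7), 3)
#>   node_id roles average_rank final_rank_position repetitions seed
#> 1  TF-006    TF        1.970                   1         200    7
#> 2  TF-009    TF        3.185                   2         200    7
#> 3  TF-007    TF        4.865                   3         200    7

find_feedback_loops(net)[1:2, ]
#>       tf   mirna   target target_is_tcof
#> 1 TF-001 miR-009 GENE-011              0
#> 2 TF-006 miR-016 GENE-001              0
```

The ranking table reads: `TF-006` attains the best (lowest) average rank —
over 200 random weight hierarchies it is, on average, the 1.97th most
influential of the 49 nodes. Each feedback-loop row is one closed circuit:
the TF regulates the miRNA, the miRNA targets the disease gene, and the gene
interacts with the TF.

The same flow is available as one call (and as a thin script,
`inst/scripts/ocmirnet-pipeline.R`):

```r
run_pipeline(list(out_dir = "run1",
                  simulate = list(seed = 42),
                  repetitions = 10000, seed = 1))
```

which writes per-window network/census/ranking/motif TSVs and a
`manifest.json` enabling exact reruns.

## Scope

TFBS scanning, promoter sequence extraction and identifier aliasing are out
of scope: the package consumes precomputed hit tables and exact-matching
identifiers. Loop sign inference (positive vs negative feedback) is not
attempted, as it depends on unknown interaction types.
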