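---
title: "Methods: network construction, stochastic node ranking and motif census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, stochastic node ranking and motif census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocmirnet)
```

## The model in brief

`ocmirnet` analyses the transcriptional control of disease-associated
miRNAs as a heterogeneous network with three interaction layers:

* **TARGETING** (directed, miRNA → protein): experimentally verified
  repression/degradation of an mRNA by a miRNA. Treated as the most reliable
  edge class.
* **REGULATION** (directed, TF → miRNA): a transcription factor with a
  predicted high-scoring binding site in the miRNA gene's promoter window.
  Directed but only predicted.
* **PPI** (undirected, protein — protein): physical interaction, the least
  informative class for directional information flow. TF–TcoF interactions
  enter the network as PPI edges; TcoF identity is kept as a node *role*,
  not a fourth edge type.

Nodes carry one or more roles (MIRNA, TF, TCOF, TARGET). miRNA and protein
identifiers are disjoint namespaces; a protein may legitimately carry
several roles (a TF that is itself a disease gene targeted by miRNAs), which
is why census role counts may sum to more than the number of distinct nodes.

### Construction assumptions

`build_network()` implements a retention cascade: a miRNA enters iff it has
at least one verified target in the disease gene list; those targets enter;
a TF enters iff it has at least one binding-site hit, with core *and* matrix
score ≥ 0.9, inside a retained miRNA's promoter window; a TcoF enters iff it
is labelled high-confidence and interacts with a retained TF. PPI edges are
then **induced** on the retained protein set — interaction partners that are
not already required by one of the relationships above are never added. This
keeps node totals equal to the union of the four role classes minus
overlaps, which is how the published per-role and total node counts relate
to each other.

Two further conventions matter for edge counts: multiple binding-site hits
of one TF in one promoter collapse to a single REGULATION edge (edges
connect node pairs, not sites), and PPIs from multiple source databases are
deduplicated on the unordered endpoint pair, with self-interactions kept
once. Identifier matching is case-preserving and exact; aliasing tables are
out of scope, and a hit table referencing a miRNA absent from the target
table is a hard error rather than a silent drop.

## Stochastic node ranking

The influence score of node $n$ for one draw of edge-type weights is

$$S_n = \sum e_{n1} + w \cdot \sum e_{n2},$$

the weighted out-degree of $n$ plus a damped sum of the weighted out-degrees
of $n$'s distinct first-degree out-neighbours. Weights attach to edge
*types*: targeting $e_t = 1$ always, regulation $e_r \sim U(0,1)$,
interaction $e_i \sim U(0, e_r)$ drawn after $e_r$, and the damping factor
$w \sim U(0,1)$, so $1 = e_t > e_r > e_i > 0$ holds in every draw by
construction ($E[e_i] = E[e_r]/2 = 1/4$, a distributional fact the test
suite checks on $10^6$ draws). One triple is drawn per repetition and shared
by all edges of a type; per-edge randomisation is deliberately not offered.
Nodes are ranked by descending $S_n$ and the procedure repeats (10,000 times
by default) with fresh draws; a node's final statistic is its average rank.
Averaging over the weight hierarchy rather than fixing one weighting is the
point of the scheme — no fixed weighting schema is defensible a priori.

Choices the formula itself does not pin down, and what this package does:

* **Undirected edges.** PPI edges count as outgoing from both endpoints in
  both degree sums. Proteins whose only edges are PPIs must receive nonzero
  scores for the ranking to discriminate among them at all.
* **Reciprocal second-degree edges.** The second-degree sum for $n$ includes
  edges of a neighbour that point *back* to $n$ (for a lone interacting pair
  D—E with $e_i = 0.25, w = 0.5$: $S_D = 0.25 + 0.5 \times 0.25 = 0.375$).
  Excluding them would complicate the formula without a textual basis in the
  method's definition; because the choice is debatable it is exposed as
  `second_degree_reciprocal = FALSE` for sensitivity analysis, and the
  brute-force oracle in the test suite covers both modes.
* **First-degree multiplicity.** $\sum e_{n1}$ is a sum over *edges*, so a
  neighbour reachable through two edge types would contribute twice; the
  second-degree sum is over *distinct* neighbours, each contributing its
  full weighted out-degree once.
* **Ties.** Tied scores receive fractional (average) ranks. This makes the
  per-repetition rank mean exactly $(N+1)/2$ — an invariant the tests
  exploit — and removes any dependence on node order. The final
  `final_rank_position` column breaks average-rank ties lexicographically by
  identifier, purely for a stable output order.
* **RNG discipline.** Draw order is fixed as $(e_r, e_i, w)$ per repetition;
  `rank_nodes()` seeds a private stream and restores the caller's RNG state,
  so results are reproducible from the `seed` column of the output alone.

A useful analytic checkpoint: in the chain TF → miRNA → gene, the terminal
gene scores 0 in every draw (average rank exactly 3) and the TF outranks
the miRNA iff $e_r + w > 1$, an event of probability exactly $1/2$ for
independent uniforms, so the TF's average rank converges to 1.5. The
acceptance tests assert this at 10,000 repetitions with a ±0.02 band
(the Monte-Carlo standard error is 0.005).

Internally the per-repetition scores are computed from per-type out-degree
count vectors and one sparse neighbour-adjacency product precomputed once
per network, so 10,000 repetitions on a ~660-node, ~20,000-edge network run
in seconds; the acceptance suite times a full published-scale build + rank +
motif census and requires it to finish within 15 minutes on one CPU.

## Motif census

* **Self-loop**: a pair (miRNA $m$, TF $f$) with REGULATION $f \to m$ and
  TARGETING $m \to f$. Reported per (miRNA, TF) pair; the count of distinct
  miRNAs involved is what comparisons against published counts should use,
  since "miRNAs that target one of their own TFs" is ambiguous between the
  two conventions (`find_self_loops()` returns the pairs, so both are
  available).
* **Feedback loop**: an ordered triple (TF $f$, miRNA $m$, target $g$) with
  REGULATION $f \to m$, TARGETING $m \to g$, a PPI $g$—$f$, $g \neq f$ and
  $g$ disease-associated. Loops are *ordered triples*: a TF–target pair
  connected through two miRNAs yields two loops. A loop whose target also
  carries the TCOF role is flagged (`target_is_tcof`) but not treated as a
  different motif, since co-factor links and plain PPIs are one edge type in
  the model. Targets that are themselves TFs are allowed as long as
  $g \neq f$.

No sign inference (activator/repressor, positive/negative feedback) is
attempted; it would require interaction-type information the input tables do
not carry. The enumeration is merge-based (regulation ⋈ targeting ⋈ PPI
lookup); the test suite checks it against an exhaustive $O(N^3)$ scan of all
ordered node triples on 50 generated networks of up to 60 nodes, and every
reported loop is re-verified against the network's edge list.

## Pathway enrichment

For loop-involved target genes (foreground, $n$ genes, $k$ in the pathway)
against the disease-gene background ($N$ genes, $K$ in the pathway), the
p-value is the exact hypergeometric upper tail
$P(X \geq k),\ X \sim \mathrm{Hypergeom}(N, K, n)$ — a one-sided Fisher
test. The method's source analysis asserts enrichment without naming a test
or printing a p-value, so the test choice is this package's own; the
recomputable quantities are the foreground and background fractions (e.g.
$31/46 \approx 0.674$ vs $125/379 \approx 0.330$ for the cell-cycle-style
configuration), and the hypergeometric tail is validated against exhaustive
subset enumeration for backgrounds up to $N = 12$. No multiple-testing
correction is applied for a single pathway; Benjamini–Hochberg is available
in `enrich_pathways()` when several pathways are tested at once.

## The synthetic-data generator

`generate_tables()` emulates the statistical structure the pipeline assumes,
not real biology: identifiers are synthetic tokens and no claim is made
about actual human genes.

What it reproduces, and the defaults' rationale:

* **Heavy-tailed targeting.** Verified-target counts per miRNA follow
  $1 + \mathrm{Geometric}$ (mean configurable; 2 by default, ~2.7 at the
  published scale where 162 miRNAs share 434 targeting edges). Observed
  networks have hub targets attracting 10–20 miRNAs, which a geometric tail
  reproduces qualitatively; the distribution is a parameterised convenience,
  not a fit.
* **Guaranteed coverage.** Every gene in the disease pool receives at least
  one targeting miRNA, so realized role counts equal configured counts and
  the ledger census is exact rather than probabilistic.
* **Nested promoter windows.** A binding site is drawn per (TF, miRNA) pair
  for the 5000nt window; with conditional probability it also lies within
  1000nt, in which case the same scores appear under both windows — the
  1000nt hit set is a subset of the 5000nt set by construction, as it must
  be for physical windows. One site per pair is modelled, consistent with
  hits collapsing to one regulation edge anyway.
* **Score straddling.** A configurable fraction of hits draws both scores
  from a failing range (default $U(0.5, 0.9)$), the rest from a passing
  range ($U(0.9, 1)$), so the ≥ 0.9 filter always has work to do.
* **Decoys.** miRNA rows targeting non-disease genes, low-confidence TcoF
  rows, and background PPIs touching never-retained proteins are all
  emitted, because the construction rules are only tested if there is
  something to exclude.
* **Role overlap.** A fraction of TFs (default 10%; 19/244 at the published
  scale, matching the published node totals' implied overlap) also appears
  in the disease gene pool, producing TARGET,TF nodes.
* **Planting.** Requested self-loops and feedback loops are wired in after
  background sampling (forced passing hits in both windows, the closing
  targeting/PPI edges) and deduplicated against it; the ledger records the
  planted lists. With background PPI density *and* hit probability set to
  zero, the planted feedback loops are provably the only ones — the
  configuration the exact-recovery test uses. With an active background,
  planted motifs are guaranteed present but independently generated edges
  may create additional, equally real loops; tests compare against the
  exhaustive oracle in that regime.

What it does **not** emulate: correlated degree structure between layers,
database-specific biases, identifier noise or aliasing, per-edge evidence
quality, and any real gene identity. A green test suite therefore
demonstrates algorithmic correctness on data with the right *shape*, not
biological validity on real tables.

## Numerical and I/O conventions

* Tables are tab-separated UTF-8 with a mandatory header, `#` comments and
  blank lines skipped; foreign layouts adapt via column mappings
  (YAML/JSON-loadable). Score bounds are validated; coercion failures
  report the physical line number.
* Networks serialise to a nodes TSV (roles as comma-joined sorted tokens,
  disease flag as 0/1) and an edges TSV; PPI edges are stored once in
  lexicographic endpoint order, which makes the round trip an identity on
  the node set, role sets, flags and edge multiset (property-tested across
  generator seeds, including PPI self-interactions).
* Degenerate inputs: an empty retained miRNA set is a hard error (nothing
  to analyse); an empty network censuses to zeros, serialises to
  headers-only files, and refuses to be ranked.
* `run_pipeline()` drives simulate-or-load → build → rank → motifs →
  (optional) enrichment per window, writes TSV/JSON artifacts and a
  `manifest.json` (inputs, seeds, thresholds, row counts, census) from which
  a run can be reproduced exactly; stage errors are prefixed with the stage
  name. The problem sizes used throughout the test suite — networks of
  15–60 nodes for oracle comparisons, one published-scale run (~660 nodes,
  ~20,000 edges, 10,000 repetitions) — keep the whole suite under a minute
  while still covering the scale the method is meant for.

## Known limitations

* Role overlap in the generator is limited to TF/TARGET (the overlap the
  published node totals imply); TCOF/TARGET overlaps are representable in
  the data model and handled by the motif annotation, but not generated.
* The reader for third-party network files requires a column mapping when
  layouts differ; it does not guess.
* The ranking treats all edges of a type identically within a repetition;
  evidence-level weighting per edge is out of scope by design.
* Enrichment assumes the foreground is a subset of the background and
  treats pathway membership as a fixed annotation; topology-aware
  enrichment is not attempted.
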