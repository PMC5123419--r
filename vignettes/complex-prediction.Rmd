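---
title: "Predicting protein complexes as dense overlapping subgraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein complexes as dense overlapping subgraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepeel)
```

## The model

A protein complex leaves two strong topological footprints in a
protein-protein interaction network (PPIN). First, as interaction
catalogues accumulate, the subgraph induced by a complex becomes *dense*:
most member pairs are eventually observed to interact, so the complex
approaches a clique with a few missing edges. Second, complexes are
*egocentric*: typically at least one member (a "leader") interacts with
almost all other members, so the complex is largely contained in the
closed 1-neighbourhood of that node. `corepeel` turns these two
observations into a search problem: find, for seed vertices `v`, the
largest node set of size at least `q` and induced density at least
`delta` inside the closed 1-neighbourhood of `v`. The family of such sets
— a *partial dense cover* of the graph — is the prediction. The sets may
overlap (proteins belong to several complexes), the cover need not touch
every vertex, and the exact problem is NP-complete, so the package
computes a heuristic approximation in four phases:

1. **Core decomposition.** The core number `C(v)` — the largest `k` such
   that `v` survives in a subgraph of minimum degree `k` — upper-bounds
   the size (minus one) of any clique or quasi-clique through `v`. It is
   computed by the classical bucket-based minimum-degree removal
   algorithm in time proportional to nodes plus edges. The *core count*
   `CC(v)` is the number of neighbours of `v` with core number at least
   `C(v)`. Seeds are processed in decreasing `(C(v), CC(v))` order, so
   leaders of large dense regions come first.
2. **Candidate construction and filtering.** The candidate for seed `v`
   is `v` plus its neighbours of core number at least `C(v)` — lower-core
   neighbours cannot belong to a quasi-clique as large as the one `C(v)`
   promises. Candidates smaller than `q` are discarded outright. Two
   cheap count filters then decide whether the expensive phase runs:
   policy 0 requires induced density strictly above `delta_low`
   (default 1/2, where Turán's theorem guarantees a large clique-like
   subgraph); policy 1 requires at least `q` members of induced degree at
   least `(q-1) * delta`, a necessary condition for a `delta`-quasi-clique
   of size `q`; policy 2 (the default) passes when either does.
3. **Peeling.** From the candidate set, nodes of minimum induced degree
   are removed one at a time until the residual density reaches `delta`
   (success) or fewer than `q` nodes remain (failure). The density rule
   is evaluated *before* each removal, so an already-dense candidate is
   returned whole. Ties among minimum-degree nodes are broken by the
   smallest sum of residual neighbour degrees `S(v)` — removing the node
   whose neighbourhood is weakest — and residual ties by ascending node
   index. A success that lost its own seed is discarded, keeping every
   cluster inside its seed's ego-network.
4. **Pruning.** Exact duplicates, sets nested in other sets, and one
   member of any pair with Jaccard similarity above `jaccard_max` are
   removed. Pairwise intersection sizes come from counting 2-paths in the
   bipartite set-element incidence structure, visiting sets in increasing
   size order; the smaller of a too-similar pair is dropped (on a size
   tie, the one seeded later).

The neighbourhood radius is fixed at 1: the egocentricity measurements
that motivate the model show most complexes already fit a radius-1
neighbourhood, and radius 2 would destroy the locality that makes the
search cheap.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 4 | minimum complex size searched for (nodes) |
| `delta` | 0.9 | minimum induced density of a reported cluster |
| `delta_low` | 0.5 | density floor of filter policy 0 (Turán bound) |
| `policy` | 2 | candidate filter: 0 density, 1 degree-count, 2 either |
| `jaccard_max` | 0.8 | similarity above which one of two predictions is dropped |

`q` and `delta` describe the complexes being sought and are the only
knobs most users should touch; with a small sample of known complexes
they can be read off directly (minimum size, typical density).
`jaccard_max` is a reporting preference, not a model parameter: the
problem definition only forbids exact duplicates, and 0.8 merges
near-duplicates while keeping genuinely overlapping complexes distinct.
Filter strictness follows the defining inequalities exactly: policy 0
rejects at density `<= delta_low` (strict pass), policy 1 passes at
degree `>= (q-1) * delta`, and all density/γ comparisons are exact
floating-point comparisons of integer degree counts against the bound —
no tolerance is applied anywhere.

## Determinism and tie-breaking

Every stage that could "pick one arbitrarily" instead falls back to
ascending node index (the order of first appearance in the input): the
seed ordering after `(C, CC)`, the peeling choice after `S(v)`, and the
victim choice in pruning after size and seed order. Two runs on the same
input therefore produce byte-identical output, which the test suite
asserts. Degenerate inputs are handled by convention stated in the
definitions: density is undefined below two nodes, so sets of size 0 or 1
always fail filtering and peeling; an empty prediction list is a valid
result (e.g. when the maximum degree is below `q - 1`).

## Evaluation measures

Predictions `P` are scored against a gold standard `B` by four measures
in `[0, 1]`, summed into an Aggregated Score in `[0, 4]`:

* **F-measure** — a cluster *matches* when its precision-recall product
  `PR(p, b) = |p∩b|² / (|p||b|)` reaches `omega` (default 0.2) for some
  complex; F is the harmonic mean of the fraction of matched clusters
  (precision) and matched complexes (recall).
* **Jaccard and PR measures** — each cluster takes its best Jaccard
  (resp. PR) score against any complex; the per-side averages are
  weighted by set size and combined by harmonic mean.
* **Semantic similarity** — the fraction of a cluster's member *pairs*
  that co-occur in at least one gold complex, size-weighted and
  harmonically combined with the symmetric complex side. This is the one
  measure that explicitly rewards placing a shared protein in several
  predicted complexes. Clusters with a single member have no pairs; they
  are scored 0 with weight 1, penalising degenerate singleton output
  rather than crashing on the empty pair set.

Collections are compared exactly as given: the package does not silently
restrict gold complexes to proteins present in the network (the
structural `complex_diagnostics()` report, which needs the graph, is the
deliberate exception). Gold complexes smaller than 3 members are
conventionally excluded from structural diagnostics; the evaluation
functions accept whatever collections the caller passes.

## GO enrichment

Each predicted cluster is assigned the annotation class minimising the
upper-tail hypergeometric probability of its overlap, computed through
`stats::phyper` in log space so that p-values far below the smallest
normalised double (regimes around 1e-190 occur with genome-sized
universes) are representable. Annotations are used as flat protein sets —
no ontology-graph propagation — and evidence codes IEA, ND and NAS are
dropped by the GAF reader by default, leaving experimentally supported
annotations. The vector of per-cluster best p-values is corrected by
Benjamini-Hochberg with the true-null proportion fixed at 1; this is
conservative relative to adaptive estimators (q-values are never
smaller), so threshold-sweep counts (`enrichment_sweep`, thresholds
1e-2 to 1e-7) are lower bounds. The background universe defaults to all
annotated proteins in the loaded namespace, not the network's node set;
pass `universe =` to `annotation_set()` to change that.

## The synthetic benchmark

`plant_complexes()` generates the ground-truth graphs used throughout
the tests: an Erdős–Rényi background `G(n, p_bg)` in which each planted
complex is densified by adding uniformly chosen missing member-pair edges
until every member reaches within-complex degree `gamma * (size - 1)` —
the quasi-clique condition the algorithm targets, realised exactly rather
than via expected-density targeting. Overlap constraints plant pairs of
complexes sharing a prescribed number of nodes. The default benchmark in
the tests and the acceptance script — `n = 200`, `p_bg = 0.05`, five
planted 10-cliques (`gamma = 1`), with 50 seeded repetitions and, for the
robustness experiment, 25% injected noise edges on 10 replicate
networks — is small enough to run in seconds yet has a background dense
enough (average degree ≈ 10) that recovery is not trivial.

What the generator emulates: high embedded density, egocentricity,
bounded overlap, and uniform spurious interactions (the noise-injection
model, matching the observation that accumulating interaction data adds
few false positives relative to the false negatives it removes). What it
does not emulate: the heavy-tailed degree distributions of real PPINs,
hub proteins shared by dozens of complexes, correlated experimental
biases, and missing edges *within* true complexes beyond what `gamma`
allows. Passing the planted-recovery tests therefore demonstrates the
machinery is correct and robust to uniform noise, not that any particular
biological catalogue will be recovered at the same rates.

Three random baselines calibrate the measures: size-matched uniform
sets (`"uniform"`), the same restricted to gold-covered proteins
(`"covered"`), and a global node relabelling of the gold standard itself
(`"relabel"`), which preserves every intersection pattern and hence
isolates pure label information. On the synthetic benchmark, semantic
similarity separates real predictions from the uniform baseline in
essentially every trial, consistent with it being the most discriminative
of the four measures.

## Design choices that were genuinely open

* **Seed membership.** The candidate passed to peeling is the seed plus
  its high-core neighbours; the seed is not protected during peeling, but
  a result that lost its seed is discarded. The seed has maximal degree
  in its own candidate, so this fires only in degenerate cases.
* **Filter density includes the seed.** The phase-II density is computed
  on the candidate *including* `v`, consistently with the size test
  counting `v`.
* **Pruning victim.** When two predictions are too similar, the smaller
  one is removed (the larger set carries more information); among equal
  sizes, the one discovered later.
* **FDR correction scope.** Correction is applied across the per-cluster
  best p-values, not across all cluster-class pairs: the reported unit is
  the cluster, and its best class is a single selected hypothesis.
* **Hypergeometric universe.** Cluster members absent from the annotation
  universe are dropped before testing, keeping the sampling model
  well-defined.

## Limitations

Maximality of the reported sets (the "largest" qualifying set per seed)
is approximated, not guaranteed — no post-hoc expansion is attempted.
Graphs are unweighted and undirected; confidence scores can gate edges at
load time (e.g. the conventional 700 cutoff for String-style scores) but
do not weight the search. Protein identifiers are opaque strings: mapping
between identifier namespaces is out of scope and must happen upstream.
The R implementation targets networks up to a few hundred thousand edges;
peeling is quadratic in candidate size in the worst case, which real
sparse PPINs avoid but pathological dense inputs need not.
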