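# corepeel

Protein complex prediction in protein–protein interaction networks
(PPINs) by core decomposition and density peeling.

## The problem

A protein complex — a set of proteins that physically associate — shows
up in a large interaction network as a *dense, ego-centric* subgraph:
most member pairs interact, and at least one member typically interacts
with nearly all of the others. `corepeel` predicts complexes by computing
an approximate *partial dense cover* of the network: a family of possibly
overlapping node sets, each of size ≥ *q*, induced density ≥ *δ*, and
contained in the closed 1-neighbourhood of a seed vertex. The exact
problem is NP-complete; the heuristic here runs in near-linear time on
sparse networks:

1. **Core decomposition** — compute core numbers *C(v)* (the largest *k*
   such that *v* lies in a subgraph of minimum degree *k*) and core
   counts *CC(v)* (neighbours of core ≥ *C(v)*); process seeds in
   decreasing (*C*, *CC*) order, so leaders of large dense regions come
   first.
2. **Candidate filtering** — the candidate for seed *v* is *v* plus its
   neighbours of core ≥ *C(v)*; cheap size/density/degree-count filters
   discard hopeless candidates.
3. **Peeling** — repeatedly remove a minimum-degree node (ties: smallest
   neighbour-degree sum *S(v)*) until the residual set reaches density
   *δ* (reported) or falls below *q* nodes (dropped).
4. **Pruning** — remove duplicate sets, nested sets, and one of any pair
   with Jaccard similarity above a threshold.

The package also ships the full evaluation stack used to benchmark such
predictions: the F-measure on the precision–recall product
PR(p,b) = |p∩b|²/(|p||b|) at threshold ω, size-weighted Jaccard and PR
matching measures, the pair co-membership semantic similarity, their sum
(the Aggregated Score in [0, 4]), hypergeometric GO-enrichment with BH
FDR correction and threshold sweeps, structural diagnostics (density,
egocentricity, overlap histograms), random prediction baselines, a
planted-quasi-clique benchmark generator with noise-edge injection, and
readers for edge-list, complex-list and GAF 2.x annotation formats.

## Worked example

Plant five 10-cliques in a 200-node random background (average degree
about 10), predict, and score against the known truth:

```r
library(corepeel)

tr  <- plant_complexes(200, 0.05, sizes = rep(10, 5), gamma = 1, seed = 7)
tr
#> Planted-complex benchmark: 200 nodes, 1251 edges, 5 complexes (sizes 10, 10, 10, 10, 10)

fit <- core_peel(tr$graph, q = 8, delta = 0.9)
fit
#> Dense-cover complex prediction (q = 8, delta = 0.9, policy = 2)
#> Graph: 200 nodes, 1251 edges
#> Predicted clusters: 5
#> Cluster sizes: min 10, median 10, max 10

head(as.data.frame(fit)[, 1:4])
#>   cluster  seed size density
#> 1       1 P0166   10       1
#> 2       2 P0040   10       1
#> 3       3 P0043   10       1
#> 4       4 P0103   10       1
#> 5       5 P0026   10       1

aggregated_score(fit, tr$truth)
#> Complex prediction quality
#>   F-measure           : 1.0000 (precision 1.0000, recall 1.0000; omega = 0.2)
#>   Jaccard measure     : 1.0000
#>   PR measure          : 1.0000
#>   Semantic similarity : 1.0000
#>   Aggregated score    : 4.0000 (of 4)
```

All five planted complexes are recovered exactly (each predicted cluster
is one planted clique, at density 1), so every matching measure is 1 and
the Aggregated Score reaches its maximum of 4. On real data the measures
trade off: precision/recall count clusters matching a gold complex at
PR ≥ ω = 0.2, the Jaccard/PR measures average best-match overlap weighted
by set size, and semantic similarity rewards correctly reproducing
proteins shared between complexes.

A thin command-line wrapper is installed at
`system.file("exec/corepeel", package = "corepeel")` with subcommands
`predict`, `evaluate`, `enrich`, `simulate` and `diagnose`:

```sh
corepeel simulate --out-prefix demo --seed 3
corepeel predict  --graph demo_edges.tsv --q 8 --delta 0.9 --out demo_clusters.txt
corepeel evaluate --clusters demo_clusters.txt --gold demo_truth.txt
```

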