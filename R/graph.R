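# Graph container and degree/density/core primitives.
#
# Protein-protein interaction networks are simple undirected graphs: external
# string protein IDs are mapped to dense integer indices at construction so
# that the linear-time core decomposition can use array-backed bookkeeping.
# All algorithms run on indices; user-facing output maps back to labels.

new_ppin <- function(adj, labels) {
  n <- length(labels)
  m <- as.integer(sum(lengths(adj)) / 2)
  structure(list(adj = adj, labels = labels, n = n, m = m), class = "ppin")
}

#' Build a protein interaction graph from an edge list
#'
#' Constructs a simple undirected graph from pairs of node labels.
#' Self-loops are dropped and duplicate or reciprocal pairs are collapsed
#' to a single undirected edge.
#'
#' @param from character vector of edge tails, or a two-column matrix /
#'   data frame of endpoint labels (in which case `to` is ignored).
#' @param to character vector of edge heads.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node labels to include.
#' @return An object of class `"ppin"`: a list with elements `adj`
#'   (per-node sorted integer neighbour lists), `labels` (external IDs),
#'   `n` (node count) and `m` (edge count).
#' @examples
#' g <- ppin_graph(c("a", "a", "b"), c("b", "c", "c"))
#' g$n  # 3
#' g$m  # 3
#' @export
ppin_graph <- function(from, to = NULL, nodes = NULL) {
  if (is.null(to)) {
    el <- as.matrix(from)
    if (ncol(el) < 2) stop("edge input needs two endpoint columns")
    to <- as.character(el[, 2])
    from <- as.character(el[, 1])
  }
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("endpoint vectors differ in length")
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  labels <- unique(c(as.character(rbind(from, to)), as.character(nodes)))
  n <- length(labels)
  adj <- rep(list(integer(0)), n)
  if (length(from)) {
    u <- match(from, labels)
    v <- match(to, labels)
    lo <- pmin(u, v)
    hi <- pmax(u, v)
    dup <- duplicated(paste(lo, hi))
    lo <- lo[!dup]
    hi <- hi[!dup]
    ends <- factor(c(lo, hi), levels = seq_len(n))
    adj <- lapply(unname(split(c(hi, lo), ends)),
                  function(x) sort(as.integer(x)))
  }
  new_ppin(adj, labels)
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf("Protein interaction graph: %d nodes, %d edges (average degree %.2f)\n",
              x$n, x$m, if (x$n > 0) 2 * x$m / x$n else NA_real_))
  invisible(x)
}

# resolve labels (character) or indices (numeric) to integer node indices
.node_idx <- function(g, v) {
  if (is.character(v)) {
    i <- match(v, g$labels)
    if (anyNA(i)) stop("unknown node label(s): ", paste(v[is.na(i)], collapse = ", "))
    i
  } else {
    i <- as.integer(v)
    if (any(i < 1L | i > g$n)) stop("node index out of range")
    i
  }
}

#' Node degrees of a ppin graph
#' @param g a `"ppin"` graph.
#' @return Integer vector of degrees named by node label.
#' @export
node_degrees <- function(g) {
  stats::setNames(as.integer(lengths(g$adj)), g$labels)
}

#' Average degree of a graph
#'
#' The average degree is `2 m / n` for a graph with `n` nodes and `m` edges.
#'
#' @param g a `"ppin"` graph.
#' @return Non-negative numeric scalar.
#' @export
average_degree <- function(g) {
  if (g$n == 0L) stop("empty graph")
  2 * g$m / g$n
}

# induced degree of each member of idx within idx
.induced_degrees <- function(g, idx) {
  inb <- logical(g$n)
  inb[idx] <- TRUE
  vapply(idx, function(v) sum(inb[g$adj[[v]]]), integer(1))
}

.induced_density <- function(g, idx) {
  k <- length(idx)
  if (k < 2L) stop("undefined density")
  sum(.induced_degrees(g, idx)) / 2 / choose(k, 2)
}

#' Density of an induced subgraph
#'
#' Ratio of the number of edges induced by a node set to the number of
#' edges of a complete graph on the same nodes. Undefined for fewer than
#' two nodes (zero denominator).
#'
#' @param g a `"ppin"` graph.
#' @param members node labels (character) or indices (numeric), at least two.
#' @return Numeric scalar in \[0, 1\].
#' @export
subgraph_density <- function(g, members) {
  .induced_density(g, .node_idx(g, members))
}

#' Test whether a node set induces a gamma-quasi-clique
#'
#' A node set Q is a gamma-quasi-clique when every member is adjacent to at
#' least `gamma * (|Q| - 1)` of the other members. The comparison is exact
#' (no tolerance): induced degrees are integers.
#'
#' @param g a `"ppin"` graph.
#' @param members node labels or indices, at least one.
#' @param gamma density relaxation parameter in \[0, 1\]; `gamma = 1`
#'   requires a clique.
#' @return Logical scalar.
#' @export
is_quasi_clique <- function(g, members, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  idx <- .node_idx(g, members)
  if (length(idx) == 0L) stop("empty node set")
  all(.induced_degrees(g, idx) >= gamma * (length(idx) - 1))
}

#' Core decomposition of a graph
#'
#' Computes the core number C(v) of every node: the largest k such that v
#' belongs to a subgraph in which every node has degree at least k. Uses
#' the bucket-based iterative minimum-degree removal algorithm, which runs
#' in time proportional to the number of nodes plus edges.
#'
#' @param g a `"ppin"` graph.
#' @return Integer vector of core numbers named by node label.
#' @export
core_numbers <- function(g) {
  n <- g$n
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  deg <- as.integer(lengths(g$adj))
  md <- max(deg)
  # bin[d + 1] = position in `ord` of the first vertex of current degree d
  counts <- tabulate(deg + 1L, nbins = md + 1L)
  bin <- integer(md + 1L)
  start <- 1L
  for (d in 0:md) {
    bin[d + 1L] <- start
    start <- start + counts[d + 1L]
  }
  ord <- order(deg)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  core <- deg
  for (i in seq_len(n)) {
    v <- ord[i]
    for (u in g$adj[[v]]) {
      if (core[u] > core[v]) {
        du <- core[u]
        pu <- pos[u]
        pw <- bin[du + 1L]
        w <- ord[pw]
        if (u != w) {
          ord[pu] <- w
          ord[pw] <- u
          pos[u] <- pw
          pos[w] <- pu
        }
        bin[du + 1L] <- bin[du + 1L] + 1L
        core[u] <- du - 1L
      }
    }
  }
  stats::setNames(core, g$labels)
}

#' Core counts
#'
#' The core count CC(v) is the number of neighbours of v whose core number
#' is at least C(v). Together with C(v) it drives the seed-processing order
#' of the complex prediction algorithm.
#'
#' @param g a `"ppin"` graph.
#' @param core core numbers as returned by [core_numbers()]; computed when
#'   missing.
#' @return Integer vector named by node label.
#' @export
core_counts <- function(g, core = core_numbers(g)) {
  core <- unname(core)
  cc <- vapply(seq_len(g$n),
               function(v) sum(core[g$adj[[v]]] >= core[v]),
               integer(1))
  stats::setNames(cc, g$labels)
}
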