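# Ground-truth generators: background graphs with planted quasi-cliques,
# random prediction baselines, and noise-edge injection.
#
# Every stochastic operation takes an integer seed and is a pure function of
# its arguments: set.seed(seed) is called on entry when a seed is given.

# sample m distinct unordered node pairs (no self-loops), excluding the
# pairs whose "lo hi" keys appear in `exclude`; rejection sampling, fine in
# the sparse regimes generated here
.sample_pairs <- function(n, m, exclude = character(0)) {
  if (m == 0L) return(list(i = integer(0), j = integer(0)))
  if (choose(n, 2) - length(exclude) < m) stop("not enough free node pairs")
  keys <- character(0)
  ii <- integer(0)
  jj <- integer(0)
  while (length(keys) < m) {
    need <- 2L * (m - length(keys)) + 10L
    a <- sample.int(n, need, replace = TRUE)
    b <- sample.int(n, need, replace = TRUE)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi)
    ok <- lo != hi & !duplicated(key) & !(key %in% exclude) & !(key %in% keys)
    keys <- c(keys, key[ok])
    ii <- c(ii, lo[ok])
    jj <- c(jj, hi[ok])
  }
  list(i = ii[seq_len(m)], j = jj[seq_len(m)])
}

# "lo hi" keys of all edges of a ppin graph
.edge_keys <- function(g) {
  unlist(lapply(seq_len(g$n), function(v) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) paste(v, nb) else character(0)
  }), use.names = FALSE)
}

#' Generate a background graph with planted dense complexes
#'
#' Draws an Erdos-Renyi background G(n, p_bg) and embeds one complex per
#' entry of `sizes`: member pairs are connected by uniformly chosen missing
#' edges until every member has within-complex degree at least
#' `gamma * (size - 1)`, so each planted set is a gamma-quasi-clique by
#' construction (a clique when `gamma = 1`). Overlaps between named
#' complexes can be requested; complexes without an overlap constraint are
#' node-disjoint.
#'
#' @param n number of nodes.
#' @param p_bg background edge probability.
#' @param sizes integer vector of complex sizes (each >= 3).
#' @param gamma within-complex quasi-clique parameter in (0.5, 1].
#' @param overlaps optional list of `c(i, j, shared)` triples: complexes i
#'   and j (1-based, i < j) must share exactly `shared` nodes.
#' @param seed integer seed; when given the generator is deterministic.
#' @return Object of class `"planted_ppin"`: list with `graph` (a
#'   `"ppin"`), `truth` (list of planted member-label sets) and `params`.
#' @examples
#' tr <- plant_complexes(100, 0.02, sizes = c(8, 8), seed = 1)
#' lengths(tr$truth)
#' @export
plant_complexes <- function(n, p_bg = 0.05, sizes = rep(10L, 5L),
                            gamma = 1, overlaps = NULL, seed = NULL) {
  stopifnot(n >= sum(sizes) - sum(vapply(overlaps, `[`, 0, 3)),
            all(sizes >= 3), gamma > 0.5, gamma <= 1,
            p_bg >= 0, p_bg <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- length(sizes)
  if (!is.null(overlaps)) {
    for (ov in overlaps) {
      if (length(ov) != 3 || ov[1] >= ov[2] || ov[2] > k ||
          ov[3] < 1 || ov[3] > min(sizes[ov[1]], sizes[ov[2]]))
        stop("infeasible overlap specification")
    }
  }

  # assign member node indices; fresh nodes never reuse earlier complexes'
  # nodes, so pairwise intersections are exactly as specified (or empty)
  truth_idx <- vector("list", k)
  used <- integer(0)
  for (i in seq_len(k)) {
    shared <- integer(0)
    for (ov in overlaps) {
      if (ov[2] == i) {
        pool <- setdiff(truth_idx[[ov[1]]], shared)
        if (length(pool) < ov[3]) stop("infeasible overlap specification")
        shared <- c(shared, sample(pool, ov[3]))
      }
    }
    free <- setdiff(seq_len(n), union(used, shared))
    fresh_n <- sizes[i] - length(shared)
    if (fresh_n < 0 || length(free) < fresh_n)
      stop("infeasible overlap specification")
    truth_idx[[i]] <- sort(c(shared, sample(free, fresh_n)))
    used <- union(used, truth_idx[[i]])
  }

  # background edges
  bg <- .sample_pairs(n, stats::rbinom(1L, choose(n, 2L), p_bg))
  ekeys <- new.env(parent = emptyenv())
  add_edge <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (is.null(ekeys[[key]])) {
      ekeys[[key]] <- TRUE
      TRUE
    } else FALSE
  }
  ei <- integer(0)
  ej <- integer(0)
  for (t in seq_along(bg$i)) {
    if (add_edge(bg$i[t], bg$j[t])) {
      ei <- c(ei, bg$i[t])
      ej <- c(ej, bg$j[t])
    }
  }

  # densify each planted complex until the quasi-clique condition holds
  for (members in truth_idx) {
    s <- length(members)
    am <- matrix(FALSE, s, s)
    key_in <- function(a, b) !is.null(ekeys[[paste(min(a, b), max(a, b))]])
    for (x in seq_len(s - 1L)) for (y in (x + 1L):s) {
      if (key_in(members[x], members[y])) am[x, y] <- am[y, x] <- TRUE
    }
    need <- ceiling(gamma * (s - 1) - 1e-9)
    repeat {
      degs <- rowSums(am)
      if (all(degs >= need)) break
      missing <- which(!am & upper.tri(am), arr.ind = TRUE)
      pick <- missing[sample.int(nrow(missing), 1L), ]
      am[pick[1], pick[2]] <- am[pick[2], pick[1]] <- TRUE
      a <- members[pick[1]]
      b <- members[pick[2]]
      if (add_edge(a, b)) {
        ei <- c(ei, a)
        ej <- c(ej, b)
      }
    }
  }

  labels <- sprintf("P%04d", seq_len(n))
  graph <- ppin_graph(labels[ei], labels[ej], nodes = labels)
  structure(list(
    graph = graph,
    truth = lapply(truth_idx, function(i) labels[i]),
    params = list(n = n, p_bg = p_bg, sizes = sizes, gamma = gamma,
                  overlaps = overlaps, seed = seed)
  ), class = "planted_ppin")
}

#' @export
print.planted_ppin <- function(x, ...) {
  cat(sprintf("Planted-complex benchmark: %d nodes, %d edges, %d complexes (sizes %s)\n",
              x$graph$n, x$graph$m, length(x$truth),
              paste(lengths(x$truth), collapse = ", ")))
  invisible(x)
}

#' Random prediction baselines
#'
#' Three null models for a gold-standard collection B over a node universe:
#' `"uniform"` draws each set uniformly from the universe, preserving B's
#' size distribution; `"covered"` does the same from the universe
#' restricted to nodes covered by some gold complex; `"relabel"` applies a
#' single global node permutation to every set, preserving sizes and all
#' intersection patterns.
#'
#' @param B gold-standard collection: list of ID vectors.
#' @param universe character vector of node labels (typically the graph's
#'   node set).
#' @param method `"uniform"`, `"covered"` or `"relabel"`.
#' @param seed integer seed for reproducibility.
#' @return List of ID vectors with the same size multiset as B.
#' @export
random_baseline <- function(B, universe,
                            method = c("uniform", "covered", "relabel"),
                            seed = NULL) {
  method <- match.arg(method)
  B <- .as_collection(B, "B")
  universe <- unique(as.character(universe))
  if (!is.null(seed)) set.seed(seed)
  if (method == "relabel") {
    if (!all(unlist(B) %in% universe))
      stop("relabel baseline requires all members in the universe")
    perm <- stats::setNames(sample(universe), universe)
    return(lapply(B, function(b) unname(perm[b])))
  }
  if (method == "covered")
    universe <- intersect(universe, unique(unlist(B, use.names = FALSE)))
  if (max(lengths(B)) > length(universe))
    stop("universe smaller than the largest gold complex")
  lapply(B, function(b) sample(universe, length(b)))
}

#' Inject random noise edges into a graph
#'
#' Adds exactly `round(fraction * m)` new edges chosen uniformly among the
#' non-adjacent node pairs; the original edges are untouched. Used to probe
#' robustness of complex prediction against spurious interactions.
#'
#' @param g a `"ppin"` graph.
#' @param fraction fraction of the current edge count to add, in \[0, 1\].
#' @param seed integer seed.
#' @return A new `"ppin"` graph on the same labelled node set.
#' @export
add_noise_edges <- function(g, fraction, seed = NULL) {
  stopifnot(inherits(g, "ppin"), fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m_new <- round(fraction * g$m)
  if (m_new == 0L) return(g)
  np <- .sample_pairs(g$n, m_new, exclude = .edge_keys(g))
  adj <- g$adj
  for (t in seq_len(m_new)) {
    adj[[np$i[t]]] <- sort(c(adj[[np$i[t]]], np$j[t]))
    adj[[np$j[t]]] <- sort(c(adj[[np$j[t]]], np$i[t]))
  }
  new_ppin(adj, g$labels)
}
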