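# The four-phase dense-cover heuristic.
#
# Phase I  : core decomposition, core counts, seed ordering.
# Phase II : per-seed candidate sets (ego neighbours of core >= C(v)) and
#            cheap count-based filters.
# Phase III: greedy peeling of minimum-degree nodes until the residual
#            candidate reaches the target density or shrinks below q.
# Phase IV : duplicate / subset / Jaccard pruning of the accepted sets.
#
# All tie-breaks fall back to ascending node index, so a run is a pure
# function of (graph, parameters).

#' Seed processing order
#'
#' Orders the nodes by decreasing core number, then decreasing core count,
#' then ascending node index. Seeds of the largest, densest regions are
#' processed first, so their clusters are discovered before fragments.
#'
#' @param g a `"ppin"` graph.
#' @param core,cc core numbers and core counts; computed when missing.
#' @return Character vector: all node labels, each exactly once.
#' @export
order_vertices <- function(g, core = core_numbers(g), cc = core_counts(g, core)) {
  g$labels[order(-unname(core), -unname(cc), seq_len(g$n))]
}

#' Candidate set of a seed node
#'
#' The candidate cluster grown from seed v: v itself plus its neighbours
#' whose core number is at least C(v). Neighbours of lower core number
#' cannot belong to a quasi-clique as large as the one C(v) promises, so
#' they are trimmed before peeling.
#'
#' @param g a `"ppin"` graph.
#' @param v a single node label or index.
#' @param core core numbers; computed when missing.
#' @return Character vector of node labels (always contains v).
#' @export
candidate_set <- function(g, v, core = core_numbers(g)) {
  vi <- .node_idx(g, v)
  stopifnot(length(vi) == 1L)
  g$labels[.cand_idx(g, unname(core), vi)]
}

.cand_idx <- function(g, core, v) {
  nb <- g$adj[[v]]
  sort(c(v, nb[core[nb] >= core[v]]))
}

#' Count-based candidate filter
#'
#' Decides whether a candidate set is worth peeling. A set smaller than q
#' always fails. Policy 0 requires induced density strictly above
#' `delta_low` (a Turan-style sufficient condition for a large dense
#' subgraph at the default 1/2). Policy 1 requires at least q members with
#' induced degree at least `(q - 1) * delta` (necessary for a
#' delta-quasi-clique of size q). Policy 2 passes when either does.
#'
#' @param g a `"ppin"` graph.
#' @param members candidate node labels or indices.
#' @param q minimum cluster size.
#' @param delta target density.
#' @param delta_low density floor for policy 0.
#' @param policy 0, 1 or 2.
#' @return Logical scalar.
#' @export
passes_filter <- function(g, members, q, delta, delta_low = 0.5, policy = 2) {
  .passes_filter_idx(g, .node_idx(g, members), q, delta, delta_low, policy)
}

.passes_filter_idx <- function(g, idx, q, delta, delta_low, policy) {
  k <- length(idx)
  if (k < q) return(FALSE)
  ideg <- .induced_degrees(g, idx)
  f0 <- function() sum(ideg) / 2 / choose(k, 2) > delta_low
  f1 <- function() sum(ideg >= (q - 1) * delta) >= q
  switch(as.character(policy),
         "0" = f0(),
         "1" = f1(),
         "2" = f0() || f1(),
         stop("policy must be 0, 1 or 2"))
}

#' Peel a candidate set down to a dense cluster
#'
#' Iteratively removes a node of minimum induced degree from the candidate
#' set until the residual density reaches `delta` (success) or the set
#' shrinks below `q` members (failure). The density stopping rule is
#' checked before each removal, so a candidate already at density >= delta
#' is returned whole. Ties among minimum-degree nodes are broken by the
#' smallest sum of residual neighbour degrees S(v), then by ascending node
#' index.
#'
#' @param g a `"ppin"` graph.
#' @param members candidate node labels or indices.
#' @param q minimum cluster size.
#' @param delta target density in (0, 1].
#' @return On success, a list with `members` (labels) and `density`;
#'   `NULL` on failure.
#' @export
peel_to_density <- function(g, members, q, delta) {
  res <- .peel_idx(g, .node_idx(g, members), q, delta)
  if (is.null(res)) return(NULL)
  list(members = g$labels[res$members], density = res$density)
}

.peel_idx <- function(g, idx, q, delta) {
  cur <- sort(unique(as.integer(idx)))
  repeat {
    k <- length(cur)
    if (k < q || k < 2L) return(NULL)
    inb <- logical(g$n)
    inb[cur] <- TRUE
    ideg <- vapply(cur, function(v) sum(inb[g$adj[[v]]]), integer(1))
    dens <- sum(ideg) / 2 / choose(k, 2)
    if (dens >= delta) return(list(members = cur, density = dens))
    cand <- cur[ideg == min(ideg)]
    if (length(cand) > 1L) {
      degmap <- integer(g$n)
      degmap[cur] <- ideg
      sv <- vapply(cand, function(v) {
        nb <- g$adj[[v]]
        sum(degmap[nb[inb[nb]]])
      }, numeric(1))
      cand <- cand[sv == min(sv)]
    }
    cur <- cur[cur != min(cand)]
  }
}

#' Prune duplicate, nested and near-duplicate clusters
#'
#' Removes exact duplicates (first occurrence kept), sets wholly contained
#' in another set, and one member of any pair whose Jaccard coefficient
#' exceeds `jaccard_max` (the smaller set is removed; on a size tie, the
#' one emitted later). Intersection sizes are obtained by counting 2-paths
#' in the bipartite set-element incidence structure, visiting sets in
#' increasing size order.
#'
#' @param clusters list of node-label vectors (or index vectors).
#' @param jaccard_max pairwise Jaccard threshold in (0, 1].
#' @return The surviving clusters, in their original order.
#' @export
prune_clusters <- function(clusters, jaccard_max = 0.8) {
  clusters[.prune_keep(clusters, jaccard_max)]
}

.prune_keep <- function(sets, jaccard_max) {
  k <- length(sets)
  if (k == 0L) return(integer(0))
  sets <- lapply(sets, function(s) sort(unique(s)))
  sizes <- lengths(sets)
  alive <- !duplicated(vapply(sets, paste, "", collapse = "\r"))
  elems <- sort(unique(unlist(sets, use.names = FALSE)))
  eidx <- lapply(sets, function(s) match(s, elems))
  # element -> ids of sets containing it (bipartite incidence)
  sp <- split(rep(seq_len(k), sizes), unlist(eidx, use.names = FALSE))
  inc_of <- rep(list(integer(0)), length(elems))
  inc_of[as.integer(names(sp))] <- unname(sp)
  for (i in order(sizes, seq_len(k))) {
    if (!alive[i]) next
    touched <- unlist(inc_of[eidx[[i]]], use.names = FALSE)
    touched <- touched[touched != i]
    if (!length(touched)) next
    ints <- tabulate(touched, nbins = k)
    for (j in which(ints > 0L)) {
      if (!alive[i]) break
      if (!alive[j]) next
      inter <- ints[j]
      if (inter == sizes[i] && sizes[j] >= sizes[i]) {
        alive[i] <- FALSE          # i is a subset of (or equal to) j
        next
      }
      if (inter == sizes[j] && sizes[j] < sizes[i]) {
        alive[j] <- FALSE          # j nested inside i
        next
      }
      jac <- inter / (sizes[i] + sizes[j] - inter)
      if (jac > jaccard_max) {
        if (sizes[i] < sizes[j]) {
          alive[i] <- FALSE
        } else if (sizes[j] < sizes[i]) {
          alive[j] <- FALSE
        } else {
          alive[max(i, j)] <- FALSE  # size tie: drop the later-seeded
        }
      }
    }
  }
  which(alive)
}

#' Predict protein complexes by core decomposition and peeling
#'
#' Computes an approximate partial dense cover of the graph: a family of
#' node sets, each of size at least `q`, induced density at least `delta`,
#' and contained in the closed 1-neighbourhood of its seed node. Every node
#' is tried as a seed in decreasing (core number, core count) order; its
#' ego-network is trimmed to neighbours of equal-or-higher core, filtered
#' by cheap count conditions, peeled down to density, and the accepted
#' sets are pruned of duplicates, nested sets and near-duplicates.
#'
#' The run is deterministic: identical inputs give identical output in
#' identical order.
#'
#' @param graph a `"ppin"` graph (see [ppin_graph()], [read_edgelist()]).
#' @param q minimum cluster size (>= 2). Complexes smaller than q are not
#'   searched for.
#' @param delta target induced density in (0, 1]; `delta = 1` demands
#'   cliques.
#' @param delta_low density floor of filter policy 0; the default 1/2
#'   follows the Turan bound guaranteeing a large clique-like subgraph.
#' @param policy candidate filter policy: 0 (density floor), 1 (degree
#'   count) or 2 (either; default).
#' @param jaccard_max pairwise Jaccard threshold above which one of two
#'   predictions is discarded.
#' @return An object of class `"core_peel"`: list with `clusters` (list of
#'   node-label vectors), `seeds`, `density`, `params`, and graph summary
#'   fields. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' pairs <- combn(letters[1:8], 2)             # a single 8-clique
#' g <- ppin_graph(pairs[1, ], pairs[2, ])
#' fit <- core_peel(g, q = 4, delta = 0.9)
#' length(fit$clusters)  # 1
#' @export
core_peel <- function(graph, q = 4, delta = 0.9, delta_low = 0.5,
                      policy = 2, jaccard_max = 0.8) {
  stopifnot(inherits(graph, "ppin"),
            length(q) == 1L, q >= 2,
            delta > 0, delta <= 1,
            delta_low >= 0, delta_low <= 1,
            policy %in% 0:2,
            jaccard_max > 0, jaccard_max <= 1)
  q <- as.integer(q)
  core <- unname(core_numbers(graph))
  cc <- unname(core_counts(graph, core))
  ord <- order(-core, -cc, seq_len(graph$n))

  members <- vector("list", 0L)
  seeds <- integer(0)
  dens <- numeric(0)
  for (v in ord) {
    cand <- .cand_idx(graph, core, v)
    if (!.passes_filter_idx(graph, cand, q, delta, delta_low, policy)) next
    res <- .peel_idx(graph, cand, q, delta)
    if (is.null(res)) next
    if (!(v %in% res$members)) next   # seed must survive peeling
    members[[length(members) + 1L]] <- res$members
    seeds <- c(seeds, v)
    dens <- c(dens, res$density)
  }
  keep <- .prune_keep(members, jaccard_max)
  structure(list(
    clusters = lapply(members[keep], function(i) graph$labels[i]),
    seeds = graph$labels[seeds[keep]],
    density = dens[keep],
    params = list(r = 1L, q = q, delta = delta, delta_low = delta_low,
                  policy = policy, jaccard_max = jaccard_max),
    graph_n = graph$n,
    graph_m = graph$m,
    call = match.call()
  ), class = "core_peel")
}

#' @export
print.core_peel <- function(x, ...) {
  p <- x$params
  cat(sprintf("Dense-cover complex prediction (q = %d, delta = %g, policy = %d)\n",
              p$q, p$delta, p$policy))
  cat(sprintf("Graph: %d nodes, %d edges\n", x$graph_n, x$graph_m))
  cat(sprintf("Predicted clusters: %d\n", length(x$clusters)))
  if (length(x$clusters)) {
    cat(sprintf("Cluster sizes: min %d, median %g, max %d\n",
                min(lengths(x$clusters)), stats::median(lengths(x$clusters)),
                max(lengths(x$clusters))))
  }
  invisible(x)
}

#' @export
summary.core_peel <- function(object, ...) {
  out <- list(
    n_clusters = length(object$clusters),
    params = object$params,
    size = if (length(object$clusters)) summary(lengths(object$clusters)),
    density = if (length(object$clusters)) summary(object$density),
    coverage = length(unique(unlist(object$clusters)))
  )
  class(out) <- "summary.core_peel"
  out
}

#' @export
print.summary.core_peel <- function(x, ...) {
  cat(sprintf("Predicted clusters: %d (covering %d distinct proteins)\n",
              x$n_clusters, x$coverage))
  if (x$n_clusters > 0) {
    cat("Cluster sizes:\n")
    print(x$size)
    cat("Induced densities:\n")
    print(x$density)
  }
  invisible(x)
}

#' @export
plot.core_peel <- function(x, ...) {
  if (!length(x$clusters)) {
    warning("no clusters to plot")
    return(invisible(x))
  }
  graphics::plot(lengths(x$clusters), x$density,
                 xlab = "cluster size", ylab = "induced density",
                 main = "Predicted clusters",
                 ylim = c(min(x$density) * 0.98, 1), ...)
  invisible(x)
}

#' @export
as.data.frame.core_peel <- function(x, ...) {
  data.frame(
    cluster = seq_along(x$clusters),
    seed = x$seeds,
    size = lengths(x$clusters),
    density = x$density,
    members = vapply(x$clusters, paste, "", collapse = " "),
    stringsAsFactors = FALSE
  )
}
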