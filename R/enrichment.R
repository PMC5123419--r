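# Hypergeometric GO-enrichment of predicted clusters.
#
# Annotations are flat protein sets per GO class (no DAG propagation). Each
# cluster is assigned its lowest-p intersecting class; the vector of
# per-cluster best p-values is corrected by Benjamini-Hochberg, and the
# threshold sweep counts clusters with q-value below 1e-2 .. 1e-7.

#' Annotation set container
#'
#' @param classes named list: GO class ID -> character vector of protein
#'   IDs.
#' @param universe background protein set M; defaults to the union of all
#'   class sets. Every class must be contained in it.
#' @param namespace optional ontology aspect label (`"BP"`, `"CC"`, `"MF"`).
#' @return Object of class `"annotation_set"`.
#' @export
annotation_set <- function(classes, universe = NULL, namespace = NA_character_) {
  stopifnot(is.list(classes))
  if (length(classes) && is.null(names(classes)))
    stop("classes must be named by GO ID")
  classes <- lapply(classes, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(classes, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  bad <- !vapply(classes, function(s) all(s %in% universe), logical(1))
  if (any(bad))
    stop("class(es) not contained in universe: ",
         paste(names(classes)[bad], collapse = ", "))
  structure(list(classes = classes, universe = universe,
                 namespace = namespace),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set (%s): %d classes over %d proteins\n",
              if (is.na(x$namespace)) "unspecified aspect" else x$namespace,
              length(x$classes), length(x$universe)))
  invisible(x)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability that a subset of size `set_size`, drawn uniformly from a
#' universe of `universe_size` proteins, intersects a class of
#' `class_size` proteins in at least `overlap` elements. Evaluated in
#' log-space through [stats::phyper()], so values far below double-precision
#' epsilon (down to about 1e-300) are returned without underflow.
#'
#' @param universe_size size of the background set M.
#' @param set_size cluster size (must not exceed `universe_size`).
#' @param class_size annotation class size (must not exceed
#'   `universe_size`).
#' @param overlap observed intersection size, between 1 and
#'   `min(set_size, class_size)`.
#' @return p-value in (0, 1].
#' @export
hyper_pvalue <- function(universe_size, set_size, class_size, overlap) {
  if (overlap < 1 || overlap > min(set_size, class_size) ||
      max(set_size, class_size) > universe_size)
    stop("invalid hypergeometric parameters")
  exp(stats::phyper(overlap - 1, class_size, universe_size - class_size,
                    set_size, lower.tail = FALSE, log.p = TRUE))
}

#' Best-enriched annotation class of a cluster
#'
#' Evaluates the hypergeometric p-value of every class the cluster
#' intersects and returns the record of the smallest one (ties broken by
#' lexicographically smaller class ID). Cluster members absent from the
#' annotation universe are dropped before testing.
#'
#' @param members character vector of cluster protein IDs.
#' @param ann an [annotation_set()].
#' @return List with `go_id`, `cluster_size`, `overlap`, `class_size`,
#'   `p_value`; or `NULL` when no class intersects the cluster.
#' @export
best_class <- function(members, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  p <- unique(as.character(members))
  if (!length(p)) stop("empty cluster")
  p <- p[p %in% ann$universe]
  if (!length(p)) return(NULL)
  M <- length(ann$universe)
  ov <- vapply(ann$classes, function(g) length(intersect(p, g)), integer(1))
  hit <- which(ov > 0L)
  if (!length(hit)) return(NULL)
  pv <- vapply(hit, function(i) {
    hyper_pvalue(M, length(p), length(ann$classes[[i]]), ov[i])
  }, numeric(1))
  ids <- names(ann$classes)[hit]
  best <- hit[order(pv, ids)][1L]
  list(go_id = names(ann$classes)[best],
       cluster_size = length(p),
       overlap = unname(ov[best]),
       class_size = length(ann$classes[[best]]),
       p_value = unname(pv[match(best, hit)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with the proportion of true nulls fixed at 1
#' (a conservative, deterministic stand-in for spline-estimated variants:
#' the resulting q-values are never smaller, so downstream threshold counts
#' are lower bounds).
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return q-values in the input order, each >= its p-value.
#' @export
correct_fdr <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-cluster enrichment table
#'
#' Assigns each cluster its best class via [best_class()] and corrects the
#' vector of per-cluster best p-values across clusters.
#'
#' @param clusters list of protein-ID vectors or a `"core_peel"` fit.
#' @param ann an [annotation_set()].
#' @return data.frame with one row per cluster: `cluster`, `go_id`,
#'   `cluster_size`, `overlap`, `class_size`, `p_value`, `q_value`
#'   (`NA` rows for unannotated clusters).
#' @export
enrich_clusters <- function(clusters, ann) {
  clusters <- .as_collection(clusters, "clusters")
  recs <- lapply(clusters, best_class, ann = ann)
  out <- data.frame(
    cluster = seq_along(clusters),
    go_id = vapply(recs, function(r) if (is.null(r)) NA_character_ else r$go_id, ""),
    cluster_size = vapply(recs, function(r) if (is.null(r)) NA_integer_ else r$cluster_size, 0L),
    overlap = vapply(recs, function(r) if (is.null(r)) NA_integer_ else r$overlap, 0L),
    class_size = vapply(recs, function(r) if (is.null(r)) NA_integer_ else r$class_size, 0L),
    p_value = vapply(recs, function(r) if (is.null(r)) NA_real_ else r$p_value, 0),
    stringsAsFactors = FALSE
  )
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- correct_fdr(out$p_value[ok])
  out
}

#' Enrichment threshold sweep
#'
#' Counts, for each q-value threshold, the clusters whose best-class
#' q-value falls strictly below it. Counts are non-increasing as the
#' threshold shrinks.
#'
#' @param clusters list of protein-ID vectors or a `"core_peel"` fit.
#' @param ann an [annotation_set()].
#' @param thresholds q-value thresholds (default `10^-(2:7)`).
#' @return data.frame with columns `threshold` and `count`.
#' @export
enrichment_sweep <- function(clusters, ann, thresholds = 10^-(2:7)) {
  tab <- enrich_clusters(clusters, ann)
  q <- tab$q_value[!is.na(tab$q_value)]
  data.frame(threshold = thresholds,
             count = vapply(thresholds, function(t) sum(q < t), integer(1)))
}
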