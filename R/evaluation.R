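# Cluster-versus-gold-standard quality measures.
#
# Collections of clusters/complexes are plain lists of character vectors of
# protein IDs. A "core_peel" fit may be passed anywhere a collection is
# expected. Four scalar measures (F-measure on the precision-recall product
# step function; size-weighted Jaccard and PR matching measures; semantic
# similarity of co-membership) are combined by summation into a single
# Aggregated Score in [0, 4].

.as_collection <- function(x, what = "collection") {
  if (inherits(x, "core_peel")) x <- x$clusters
  if (!is.list(x)) stop(what, " must be a list of ID vectors")
  if (length(x) == 0L) stop("empty collection")
  x <- lapply(x, function(s) unique(as.character(s)))
  if (any(lengths(x) == 0L)) stop("empty set in ", what)
  x
}

#' Precision-recall product of two sets
#'
#' `PR(p, b) = |p intersect b|^2 / (|p| * |b|)`, the product of the
#' precision and the recall of predicting complex b by cluster p.
#'
#' @param p,b non-empty character vectors of protein IDs.
#' @return Numeric scalar in \[0, 1\].
#' @export
pr_product <- function(p, b) {
  p <- unique(as.character(p))
  b <- unique(as.character(b))
  if (!length(p) || !length(b)) stop("empty set")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Jaccard coefficient of two sets
#' @param p,b non-empty character vectors of protein IDs.
#' @return Numeric scalar in \[0, 1\].
#' @export
jaccard_coef <- function(p, b) {
  p <- unique(as.character(p))
  b <- unique(as.character(b))
  if (!length(p) || !length(b)) stop("empty set")
  i <- length(intersect(p, b))
  i / (length(p) + length(b) - i)
}

# |P| x |B| matrix of pairwise scores
.score_matrix <- function(P, B, fun) {
  vapply(B, function(b) vapply(P, function(p) fun(p, b), numeric(1)),
         numeric(length(P)))
}

#' F-measure of complex prediction
#'
#' A cluster p matches when some gold complex b has `pr_product(p, b) >=
#' omega`, and symmetrically for complexes. Precision is the fraction of
#' matched clusters, recall the fraction of matched complexes, and F their
#' harmonic mean (0 when both are 0).
#'
#' @param P predicted clusters: list of ID vectors or a `"core_peel"` fit.
#' @param B gold-standard complexes: list of ID vectors.
#' @param omega matching threshold on the precision-recall product
#'   (default 0.2, the conventional value; method rankings are reported to
#'   be robust to it).
#' @return List with `precision`, `recall`, `f`.
#' @export
f_measure <- function(P, B, omega = 0.2) {
  P <- .as_collection(P, "P")
  B <- .as_collection(B, "B")
  sm <- matrix(.score_matrix(P, B, pr_product), nrow = length(P))
  np <- sum(apply(sm, 1, max) >= omega)
  nb <- sum(apply(sm, 2, max) >= omega)
  precision <- np / length(P)
  recall <- nb / length(B)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f = f)
}

#' Size-weighted best-match measure
#'
#' For each cluster take its best score against any complex; average these
#' weighted by cluster size; do the same from the complex side; return the
#' harmonic mean of the two sides (0 when either side is 0). With
#' `score = "jaccard"` this is the Jaccard measure; with `score = "pr"` the
#' PR measure.
#'
#' @param P predicted clusters (list of ID vectors or `"core_peel"` fit).
#' @param B gold-standard complexes.
#' @param score `"jaccard"` or `"pr"`.
#' @return Numeric scalar in \[0, 1\].
#' @export
matching_measure <- function(P, B, score = c("jaccard", "pr")) {
  fun <- switch(match.arg(score), jaccard = jaccard_coef, pr = pr_product)
  P <- .as_collection(P, "P")
  B <- .as_collection(B, "B")
  sm <- matrix(.score_matrix(P, B, fun), nrow = length(P))
  side_p <- sum(lengths(P) * apply(sm, 1, max)) / sum(lengths(P))
  side_b <- sum(lengths(B) * apply(sm, 2, max)) / sum(lengths(B))
  if (side_p == 0 || side_b == 0) 0 else
    2 * side_p * side_b / (side_p + side_b)
}

# element -> indices of the sets of X containing it
.member_index <- function(X) {
  split(rep(seq_along(X), lengths(X)), unlist(X, use.names = FALSE))
}

# size-weighted mean, over sets of X, of the fraction of unordered member
# pairs co-occurring in at least one set of Y; singletons contribute 0 with
# weight 1 (no pair exists, degenerate prediction is penalised)
.co_membership_side <- function(X, Y) {
  yind <- .member_index(Y)
  den <- vapply(X, function(s) {
    if (length(s) < 2L) return(0)
    pr <- utils::combn(s, 2)
    hits <- vapply(seq_len(ncol(pr)), function(j) {
      a <- yind[[pr[1, j]]]
      b <- yind[[pr[2, j]]]
      !is.null(a) && !is.null(b) && length(intersect(a, b)) > 0L
    }, logical(1))
    mean(hits)
  }, numeric(1))
  sum(lengths(X) * den) / sum(lengths(X))
}

#' Semantic similarity of two collections
#'
#' For each cluster, the fraction of its unordered member pairs that
#' co-occur in at least one gold complex, size-weighted over clusters;
#' symmetrically for complexes against clusters; harmonic mean of the two
#' sides. This is the only measure that explicitly rewards recovering
#' proteins shared by several complexes.
#'
#' @param P predicted clusters (list of ID vectors or `"core_peel"` fit).
#' @param B gold-standard complexes.
#' @return Numeric scalar in \[0, 1\].
#' @export
semantic_similarity <- function(P, B) {
  P <- .as_collection(P, "P")
  B <- .as_collection(B, "B")
  side_p <- .co_membership_side(P, B)
  side_b <- .co_membership_side(B, P)
  if (side_p == 0 || side_b == 0) 0 else
    2 * side_p * side_b / (side_p + side_b)
}

#' All four quality measures and the Aggregated Score
#'
#' @param P predicted clusters (list of ID vectors or `"core_peel"` fit).
#' @param B gold-standard complexes.
#' @param omega F-measure matching threshold.
#' @return Object of class `"complex_eval"`: list with `precision`,
#'   `recall`, `f_measure`, `jaccard_measure`, `pr_measure`,
#'   `semantic_similarity` and `aggregated_score` (their sum, in \[0, 4\]).
#' @examples
#' P <- list(c("a", "b", "c"))
#' B <- list(c("a", "b", "c", "d"), c("x", "y", "z"))
#' aggregated_score(P, B)
#' @export
aggregated_score <- function(P, B, omega = 0.2) {
  fm <- f_measure(P, B, omega)
  jm <- matching_measure(P, B, "jaccard")
  pm <- matching_measure(P, B, "pr")
  ss <- semantic_similarity(P, B)
  structure(list(
    precision = fm$precision,
    recall = fm$recall,
    f_measure = fm$f,
    jaccard_measure = jm,
    pr_measure = pm,
    semantic_similarity = ss,
    aggregated_score = fm$f + jm + pm + ss,
    omega = omega
  ), class = "complex_eval")
}

#' @export
print.complex_eval <- function(x, ...) {
  cat("Complex prediction quality\n")
  cat(sprintf("  F-measure           : %.4f (precision %.4f, recall %.4f; omega = %g)\n",
              x$f_measure, x$precision, x$recall, x$omega))
  cat(sprintf("  Jaccard measure     : %.4f\n", x$jaccard_measure))
  cat(sprintf("  PR measure          : %.4f\n", x$pr_measure))
  cat(sprintf("  Semantic similarity : %.4f\n", x$semantic_similarity))
  cat(sprintf("  Aggregated score    : %.4f (of 4)\n", x$aggregated_score))
  invisible(x)
}

#' Structural diagnostics of complexes embedded in a graph
#'
#' Restricts each complex to the proteins present in the graph, then
#' reports, over complexes of at least `min_size` surviving members: the
#' induced density of each complex with counts above 0.9 and 0.5 (strict);
#' egocentricity — whether some member is adjacent to at least 90% (resp.
#' 50%) of the other members; and, over all restricted complexes, the
#' number of proteins covered by exactly one, two, three, or more than
#' three complexes.
#'
#' @param g a `"ppin"` graph.
#' @param B complexes: list of protein-ID vectors.
#' @param min_size minimum restricted complex size for the density and
#'   egocentricity statistics (default 3).
#' @return Object of class `"complex_diagnostics"`.
#' @export
complex_diagnostics <- function(g, B, min_size = 3) {
  B <- .as_collection(B, "B")
  restr <- lapply(B, function(b) b[b %in% g$labels])
  big <- restr[lengths(restr) >= min_size]
  per <- data.frame(
    size = lengths(big),
    density = vapply(big, function(b) .induced_density(g, .node_idx(g, b)),
                     numeric(1)),
    ego_frac = vapply(big, function(b) {
      idx <- .node_idx(g, b)
      max(.induced_degrees(g, idx)) / (length(idx) - 1)
    }, numeric(1))
  )
  covered <- unlist(restr[lengths(restr) > 0L], use.names = FALSE)
  mult <- table(covered)
  structure(list(
    n_complexes = length(big),
    size = if (nrow(per)) c(min = min(per$size), mean = mean(per$size),
                            max = max(per$size)),
    per_complex = per,
    density_gt_90 = sum(per$density > 0.9),
    density_gt_50 = sum(per$density > 0.5),
    ego_ge_90 = sum(per$ego_frac >= 0.9),
    ego_ge_50 = sum(per$ego_frac >= 0.5),
    n_proteins = length(mult),
    overlap = c(`1` = sum(mult == 1), `2` = sum(mult == 2),
                `3` = sum(mult == 3), `>3` = sum(mult > 3))
  ), class = "complex_diagnostics")
}

#' @export
print.complex_diagnostics <- function(x, ...) {
  cat(sprintf("Complexes of size >= 3 in graph: %d\n", x$n_complexes))
  if (x$n_complexes > 0) {
    cat(sprintf("  Size: min %d, mean %.2f, max %d\n",
                x$size[["min"]], x$size[["mean"]], x$size[["max"]]))
    cat(sprintf("  Density > 0.9: %d;  > 0.5: %d\n",
                x$density_gt_90, x$density_gt_50))
    cat(sprintf("  With a center adjacent to >= 90%% of members: %d;  >= 50%%: %d\n",
                x$ego_ge_90, x$ego_ge_50))
  }
  cat(sprintf("Proteins covered: %d (in 1/2/3/>3 complexes: %s)\n",
              x$n_proteins, paste(x$overlap, collapse = "/")))
  invisible(x)
}
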