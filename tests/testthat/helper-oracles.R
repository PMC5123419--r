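# Small graph builders and definitional oracles used across tests.
# Oracles are deliberately naive re-statements of definitions, independent
# of the package's algorithmic code paths.

clique_ppin <- function(k, labels = sprintf("v%02d", seq_len(k))) {
  pr <- combn(labels, 2)
  ppin_graph(pr[1, ], pr[2, ])
}

path_ppin <- function(k, labels = sprintf("v%02d", seq_len(k))) {
  ppin_graph(labels[-k], labels[-1])
}

cycle_ppin <- function(k, labels = sprintf("v%02d", seq_len(k))) {
  ppin_graph(labels, labels[c(2:k, 1)])
}

star_ppin <- function(n_leaves) {
  ppin_graph(rep("hub", n_leaves), sprintf("leaf%02d", seq_len(n_leaves)))
}

# Erdos-Renyi graph over all pairs (keeps isolated nodes)
er_ppin <- function(n, p) {
  labels <- sprintf("v%03d", seq_len(n))
  pr <- combn(labels, 2)
  keep <- stats::runif(ncol(pr)) < p
  ppin_graph(pr[1, keep], pr[2, keep], nodes = labels)
}

# Definitional core-number oracle: for each k, repeatedly delete any node of
# residual degree < k; survivors have core number >= k.
naive_core <- function(g) {
  n <- g$n
  core <- integer(n)
  if (n == 0L) return(core)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- vapply(seq_len(n), function(v)
        if (alive[v]) sum(alive[g$adj[[v]]]) else n, integer(1))
      bad <- alive & deg < k
      if (!any(bad)) break
      alive[bad] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
  }
  core
}

# edge count among a set of node indices, by direct pair lookup
naive_edge_count <- function(g, idx) {
  if (length(idx) < 2) return(0L)
  pr <- combn(idx, 2)
  sum(vapply(seq_len(ncol(pr)), function(j)
    pr[2, j] %in% g$adj[[pr[1, j]]], logical(1)))
}

# Brute-force size-weighted best-match evaluator (explicit loops; mirror of
# the definition, not of the implementation)
brute_matching <- function(P, B, coef = c("jaccard", "pr")) {
  coef <- match.arg(coef)
  sc <- function(p, b) {
    i <- length(intersect(p, b))
    if (coef == "jaccard") i / length(union(p, b))
    else i^2 / (length(p) * length(b))
  }
  side <- function(X, Y) {
    num <- 0
    for (x in X) {
      best <- 0
      for (y in Y) best <- max(best, sc(x, y))
      num <- num + length(x) * best
    }
    num / sum(lengths(X))
  }
  a <- side(P, B)
  b <- side(B, P)
  if (a == 0 || b == 0) 0 else 2 * a * b / (a + b)
}

# Exhaustive hypergeometric tail: fraction of all size-p subsets of 1..M
# whose intersection with 1..g_size has size >= k.
enum_hyper_tail <- function(M, p_size, g_size, k) {
  subs <- combn(M, p_size)
  mean(colSums(subs <= g_size) >= k)
}
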