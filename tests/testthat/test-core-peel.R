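# K4 with a pendant node: the standard small fixture for Phase I/II checks
k4_pendant <- function() {
  pr <- combn(c("a", "b", "c", "d"), 2)
  ppin_graph(c(pr[1, ], "a"), c(pr[2, ], "pend"))
}

test_that("vertex order ranks by core, core count, then node index", {
  g <- k4_pendant()
  ord <- order_vertices(g)
  expect_setequal(ord, g$labels)
  expect_equal(ord[5], "pend")           # lowest core last
  # two disjoint cliques: all K5 nodes before all K3 nodes
  p5 <- combn(sprintf("a%d", 1:5), 2)
  p3 <- combn(sprintf("b%d", 1:3), 2)
  g2 <- ppin_graph(c(p5[1, ], p3[1, ]), c(p5[2, ], p3[2, ]))
  ord2 <- order_vertices(g2)
  expect_equal(ord2[1:5], sprintf("a%d", 1:5))
  # equal (C, CC) everywhere: ascending node index
  k4 <- clique_ppin(4)
  expect_equal(order_vertices(k4), k4$labels)
})

test_that("candidate sets keep the seed plus equal-or-higher-core neighbours", {
  k4 <- clique_ppin(4)
  expect_setequal(candidate_set(k4, k4$labels[2]), k4$labels)
  g <- k4_pendant()
  expect_setequal(candidate_set(g, "pend"), c("pend", "a"))
  g_iso <- ppin_graph("a", "b", nodes = "solo")
  expect_equal(candidate_set(g_iso, "solo"), "solo")
})

test_that("filter policies implement the size, density and degree conditions", {
  k5 <- clique_ppin(5)
  # size test dominates every policy
  for (pol in 0:2)
    expect_false(passes_filter(k5, k5$labels[1:4], q = 5, delta = 0.9,
                               policy = pol))
  # clique of size q passes policy 0 (density 1 > 0.5)
  expect_true(passes_filter(k5, k5$labels, q = 5, delta = 0.9,
                            delta_low = 0.5, policy = 0))
  # star: only the hub reaches degree (q-1)*delta for q >= 3 -> policy 1 fails
  st <- star_ppin(6)  # q + 3 nodes with q = 4
  expect_false(passes_filter(st, st$labels, q = 4, delta = 0.9, policy = 1))
  # ... and its density 6/21 <= 0.5 fails policy 0 and hence policy 2
  expect_false(passes_filter(st, st$labels, q = 4, delta = 0.9, policy = 0))
  expect_false(passes_filter(st, st$labels, q = 4, delta = 0.9, policy = 2))
  # policy 2 passes when either branch passes
  expect_true(passes_filter(k5, k5$labels, q = 5, delta = 0.9, policy = 2))
  # strictness: density exactly delta_low fails policy 0
  p3 <- path_ppin(3)
  expect_false(passes_filter(p3, p3$labels, q = 3, delta = 0.5,
                             delta_low = 2 / 3, policy = 0))
})

test_that("peeling removes low-degree nodes and stops at the density rule", {
  # already-dense candidate returned unchanged
  k5 <- clique_ppin(5)
  res <- peel_to_density(k5, k5$labels, q = 5, delta = 1)
  expect_setequal(res$members, k5$labels)
  expect_equal(res$density, 1)
  # K6 + pendant: pendant peeled first, clique returned at density 1
  pr <- combn(sprintf("c%d", 1:6), 2)
  g <- ppin_graph(c(pr[1, ], "c1"), c(pr[2, ], "pend"))
  res <- peel_to_density(g, g$labels, q = 4, delta = 1)
  expect_setequal(res$members, sprintf("c%d", 1:6))
  # a path can never reach density 0.9 before dropping below q
  p6 <- path_ppin(6)
  expect_null(peel_to_density(p6, p6$labels, q = 4, delta = 0.9))
})

test_that("peeling tie-break prefers the minimum neighbour-degree sum", {
  # triangle a-b-c with pendant p1 on a and pendant p2 on b, and an extra
  # edge making deg(c)=2: all of p1,p2 have degree 1; S(p1)=deg(a), S(p2)=deg(b)
  g <- ppin_graph(c("a", "b", "c", "a", "b", "b"),
                  c("b", "c", "a", "p1", "p2", "x"))
  # degrees: a=3, b=4, c=2, p1=1, p2=1, x=1
  # min-degree nodes {p1, p2, x}; S(p1)=3, S(p2)=4, S(x)=4
  # after removing p1 the same logic applies to the rest
  res <- peel_to_density(g, g$labels, q = 3, delta = 1)
  expect_setequal(res$members, c("a", "b", "c"))
})

test_that("pruning removes duplicates, subsets and near-duplicates deterministically", {
  expect_equal(prune_clusters(list(c("1", "2", "3"), c("1", "2", "3"))),
               list(c("1", "2", "3")))
  expect_equal(prune_clusters(list(c("1", "2", "3", "4"), c("2", "3", "4"))),
               list(c("1", "2", "3", "4")))
  # Jaccard 9/11 > 0.8: later-seeded of the equal-size pair removed
  a <- as.character(1:10)
  b <- as.character(c(1:9, 11))
  expect_equal(prune_clusters(list(a, b), jaccard_max = 0.8), list(a))
  expect_equal(prune_clusters(list(b, a), jaccard_max = 0.8), list(b))
  # ... and kept when the threshold admits them
  expect_equal(prune_clusters(list(a, b), jaccard_max = 0.85), list(a, b))
  # smaller of an unequal near-duplicate pair is removed regardless of order
  big <- as.character(1:10)
  small <- as.character(1:9)
  expect_equal(prune_clusters(list(small, c(big, "99")),
                              jaccard_max = 0.5),
               list(c(big, "99")))
})

test_that("end-to-end prediction recovers cliques and respects trivial bounds", {
  # single K8: every seed converges to the same set, dedup collapses to one
  k8 <- clique_ppin(8)
  fit <- core_peel(k8, q = 4, delta = 0.9)
  expect_length(fit$clusters, 1)
  expect_setequal(fit$clusters[[1]], k8$labels)
  expect_equal(fit$density, 1)
  # two disjoint K6
  p1 <- combn(sprintf("a%d", 1:6), 2)
  p2 <- combn(sprintf("b%d", 1:6), 2)
  g2 <- ppin_graph(c(p1[1, ], p2[1, ]), c(p1[2, ], p2[2, ]))
  fit2 <- core_peel(g2, q = 4, delta = 0.9)
  expect_length(fit2$clusters, 2)
  expect_setequal(fit2$clusters[[1]], sprintf("a%d", 1:6))
  expect_setequal(fit2$clusters[[2]], sprintf("b%d", 1:6))
  # max degree < q - 1: every candidate set is too small
  p10 <- path_ppin(10)
  expect_length(core_peel(p10, q = 4, delta = 0.5)$clusters, 0)
})

test_that("every emitted cluster satisfies the dense-cover conditions", {
  set.seed(99)
  for (rep in 1:15) {
    g <- er_ppin(sample(25:60, 1), stats::runif(1, 0.1, 0.3))
    q <- sample(3:6, 1)
    delta <- stats::runif(1, 0.6, 1)
    fit <- core_peel(g, q = q, delta = delta)
    for (i in seq_along(fit$clusters)) {
      cl <- fit$clusters[[i]]
      seed <- fit$seeds[i]
      expect_gte(length(cl), q)
      idx <- match(cl, g$labels)
      dens <- naive_edge_count(g, idx) / choose(length(idx), 2)
      expect_gte(dens, delta)
      expect_equal(dens, fit$density[i])
      expect_true(seed %in% cl)
      ego <- c(seed, g$labels[g$adj[[match(seed, g$labels)]]])
      expect_true(all(cl %in% ego))
    }
  }
})

test_that("overlapping planted cliques are both recovered as distinct clusters", {
  tr <- plant_complexes(40, 0.02, sizes = c(8, 8), gamma = 1,
                        overlaps = list(c(1, 2, 3)), seed = 5)
  expect_length(intersect(tr$truth[[1]], tr$truth[[2]]), 3)
  fit <- core_peel(tr$graph, q = 5, delta = 0.9)
  match_idx <- vapply(tr$truth, function(b)
    which.max(vapply(fit$clusters, jaccard_coef, numeric(1), b = b)),
    integer(1))
  best <- vapply(seq_along(tr$truth), function(i)
    jaccard_coef(fit$clusters[[match_idx[i]]], tr$truth[[i]]), numeric(1))
  expect_true(all(best >= 0.8))
  expect_length(unique(match_idx), 2)
})

test_that("prediction is deterministic", {
  tr <- plant_complexes(120, 0.05, sizes = c(8, 10, 12), seed = 21)
  f1 <- core_peel(tr$graph, q = 6, delta = 0.85)
  f2 <- core_peel(tr$graph, q = 6, delta = 0.85)
  expect_identical(f1$clusters, f2$clusters)
  expect_identical(f1$seeds, f2$seeds)
  expect_identical(f1$density, f2$density)
})
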