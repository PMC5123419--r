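test_that("precision-recall product and Jaccard coefficient match arithmetic", {
  s <- letters[1:4]
  expect_equal(pr_product(s, s), 1)
  expect_equal(pr_product(letters[1:3], letters[10:12]), 0)
  expect_equal(pr_product(letters[1:4], letters[2:7]), 9 / 24)  # |int| = 3
  expect_equal(jaccard_coef(letters[1:4], letters[2:7]), 3 / 7)
  expect_error(pr_product(character(0), s), "empty")
})

test_that("F-measure counts threshold matches on both sides", {
  B <- list(c("a", "b", "c", "d"), c("x", "y", "z"))
  P <- list(c("a", "b", "c"))
  fm <- f_measure(P, B, omega = 0.2)   # PR(p1, b1) = 9/12 = 0.75
  expect_equal(fm$precision, 1)
  expect_equal(fm$recall, 0.5)
  expect_equal(fm$f, 2 / 3)
  # identity and total mismatch
  expect_equal(f_measure(B, B)$f, 1)
  fm0 <- f_measure(list(c("q", "r", "s")), B)
  expect_equal(fm0$f, 0)
  expect_error(f_measure(list(), B), "empty")
  # adding unmatched duplicate clusters can only lower precision
  P2 <- c(P, list(c("q1", "q2"), c("q1", "q2")))
  expect_lt(f_measure(P2, B)$precision, fm$precision)
})

test_that("size-weighted matching measures reproduce hand-worked values", {
  P <- list(c("a", "b"))
  B <- list(c("a", "b", "c", "d"))
  # Jac = 0.5 on both sides -> harmonic mean 0.5
  expect_equal(matching_measure(P, B, "jaccard"), 0.5)
  expect_equal(matching_measure(B, B, "jaccard"), 1)
  expect_equal(matching_measure(B, B, "pr"), 1)
  expect_equal(matching_measure(list(c("u", "v")), B, "jaccard"), 0)
})

test_that("matching measures agree with a brute-force evaluator on random families", {
  set.seed(7)
  ids <- sprintf("p%02d", 1:25)
  for (rep in 1:20) {
    P <- lapply(seq_len(sample(2:5, 1)), function(i) sample(ids, sample(2:6, 1)))
    B <- lapply(seq_len(sample(2:5, 1)), function(i) sample(ids, sample(2:6, 1)))
    expect_equal(matching_measure(P, B, "jaccard"), brute_matching(P, B, "jaccard"))
    expect_equal(matching_measure(P, B, "pr"), brute_matching(P, B, "pr"))
  }
  # value 1 iff the two families coincide (as sets of sets)
  fam <- list(c("a", "b", "c"), c("c", "d"))
  expect_equal(matching_measure(fam, rev(fam), "jaccard"), 1)
  expect_lt(matching_measure(fam, list(c("a", "b", "c"), c("c", "e")), "jaccard"), 1)
})

test_that("semantic similarity matches the worked co-membership example", {
  P <- list(c("a", "b", "c"))
  B <- list(c("a", "b"), c("c", "d"))
  # Den(p, B) = 1/3; Density(B) = 0.5 -> harmonic mean 0.4
  expect_equal(semantic_similarity(P, B), 0.4)
  # identity with all sizes >= 2
  expect_equal(semantic_similarity(B, B), 1)
  # no co-occurring pair anywhere
  expect_equal(semantic_similarity(P, list(c("a", "x"), c("b", "y"))), 0)
})

test_that("aggregated score composes the four measures", {
  B <- list(c("a", "b", "c", "d"), c("x", "y", "z"))
  ev <- aggregated_score(B, B)
  expect_equal(ev$aggregated_score, 4)
  expect_equal(ev$f_measure, 1)
  dis <- aggregated_score(list(c("q", "r", "s")), B)
  expect_equal(dis$aggregated_score, 0)
  P <- list(c("a", "b", "c"))
  ev2 <- aggregated_score(P, B)
  expect_equal(ev2$aggregated_score,
               ev2$f_measure + ev2$jaccard_measure + ev2$pr_measure +
                 ev2$semantic_similarity)
  expect_equal(ev2$f_measure, 2 / 3)
})

test_that("all measures are invariant under protein relabelling", {
  set.seed(13)
  ids <- sprintf("p%02d", 1:20)
  P <- lapply(1:3, function(i) sample(ids, sample(3:6, 1)))
  B <- lapply(1:4, function(i) sample(ids, sample(3:6, 1)))
  perm <- stats::setNames(sample(ids), ids)
  Pp <- lapply(P, function(s) unname(perm[s]))
  Bp <- lapply(B, function(s) unname(perm[s]))
  expect_equal(f_measure(Pp, Bp)$f, f_measure(P, B)$f)
  expect_equal(matching_measure(Pp, Bp, "jaccard"),
               matching_measure(P, B, "jaccard"))
  expect_equal(matching_measure(Pp, Bp, "pr"), matching_measure(P, B, "pr"))
  expect_equal(semantic_similarity(Pp, Bp), semantic_similarity(P, B))
  for (m in c("f_measure", "jaccard_measure", "pr_measure",
              "semantic_similarity")) {
    v <- aggregated_score(P, B)[[m]]
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("diagnostics report density, egocentricity and overlap histograms", {
  tr <- plant_complexes(60, 0, sizes = c(5, 6, 7), gamma = 1, seed = 2)
  d <- complex_diagnostics(tr$graph, tr$truth)
  expect_equal(d$n_complexes, 3)
  expect_equal(d$density_gt_90, 3)   # planted cliques
  expect_equal(d$ego_ge_90, 3)
  expect_equal(unname(d$overlap), c(18, 0, 0, 0))
  # 4-node path embedded: density exactly 0.5 is NOT counted (strict >)
  g <- path_ppin(4)
  d2 <- complex_diagnostics(g, list(g$labels))
  expect_equal(d2$density_gt_50, 0)
  expect_equal(d2$density_gt_90, 0)
  # three complexes sharing one protein put it in the "3" bin
  g3 <- clique_ppin(7)
  lb <- g3$labels
  B3 <- list(lb[1:3], lb[c(1, 4, 5)], lb[c(1, 6, 7)])
  d3 <- complex_diagnostics(g3, B3)
  expect_equal(unname(d3$overlap), c(6, 0, 1, 0))
  # members absent from the graph are dropped before measuring
  d4 <- complex_diagnostics(g3, list(c(lb[1:3], "ghost")))
  expect_equal(d4$per_complex$size, 3)
})
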