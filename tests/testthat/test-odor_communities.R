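test_that("co-annotation graphs connect labels through shared molecules", {
  g1 <- buildOdorGraph(moleculesFromLabelSets(list(c("sweet", "caramel"))))
  expect_equal(edgeCount(g1), 1)
  expect_equal(adjacencyMatrix(g1, weighted = TRUE)["sweet", "caramel"], 1L)

  g2 <- buildOdorGraph(moleculesFromLabelSets(list(c("a", "b"), c("b", "c"))))
  A <- adjacencyMatrix(g2)
  expect_equal(A["a", "b"], 1L)
  expect_equal(A["b", "c"], 1L)
  expect_equal(A["a", "c"], 0L)

  g3 <- buildOdorGraph(moleculesFromLabelSets(list("a", "b")))
  expect_equal(edgeCount(g3), 0)
  expect_error(buildOdorGraph(moleculesFromLabelSets(list(character(0)))),
               "no odor labels")
})

twoTriangles <- function() {
  buildOdorGraph(moleculesFromLabelSets(list(c("a", "b", "c"),
                                             c("d", "e", "f"))))
}

test_that("modularity reproduces closed-form values", {
  g <- twoTriangles()
  one <- stats::setNames(rep(1L, 6), c("a", "b", "c", "d", "e", "f"))
  expect_equal(graphModularity(g, one), 0, tolerance = 1e-12)
  split <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                           c("a", "b", "c", "d", "e", "f"))
  expect_equal(graphModularity(g, split), 0.5, tolerance = 1e-12)

  tri <- buildOdorGraph(moleculesFromLabelSets(list(c("x", "y", "z"))))
  singles <- stats::setNames(1:3, c("x", "y", "z"))
  expect_equal(graphModularity(tri, singles), -1 / 3, tolerance = 1e-12)

  lonely <- buildOdorGraph(moleculesFromLabelSets(list("a", "b")))
  expect_error(graphModularity(lonely, stats::setNames(1:2, c("a", "b"))),
               "edgeless")
})

test_that("matrix modularity equals the explicit double-sum oracle", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    A <- randomGraphAdjacency(n)
    if (sum(A) == 0) next
    g <- graphFromAdjacency(A)
    memb <- stats::setNames(sample(1:3, n, replace = TRUE), rownames(A))
    expect_equal(graphModularity(g, memb), bruteModularity(A, memb),
                 tolerance = 1e-12)
  }
})

test_that("modularity agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:20) {
    A <- randomGraphAdjacency(sample(4:14, 1))
    if (sum(A) == 0) next
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    memb <- sample(1:3, nrow(A), replace = TRUE)
    expect_equal(
      graphModularity(graphFromAdjacency(A),
                      stats::setNames(memb, rownames(A))),
      igraph::modularity(ig, memb), tolerance = 1e-12)
  }
})

test_that("greedy merging recovers planted cliques and trivial cases", {
  p <- greedyModularityPartition(twoTriangles())
  memb <- communityOf(p)
  expect_equal(nCommunities(p), 2L)
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(memb[c("d", "e", "f")])), 1L)
  expect_equal(modularityQ(p), 0.5, tolerance = 1e-12)

  pair <- buildOdorGraph(moleculesFromLabelSets(list(c("a", "b"))))
  p2 <- greedyModularityPartition(pair)
  expect_equal(nCommunities(p2), 1L)     # Q = 0 beats singletons at -1/2
  expect_equal(modularityQ(p2), 0, tolerance = 1e-12)

  expect_error(greedyModularityPartition(
    buildOdorGraph(moleculesFromLabelSets(list("a", "b")))), "edgeless")
})

test_that("incremental gain bookkeeping matches from-scratch recomputation", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    A <- randomGraphAdjacency(n, pEdge = stats::runif(1, 0.15, 0.6))
    if (sum(A) == 0) next
    g <- graphFromAdjacency(A)
    p <- greedyModularityPartition(g, keepTrace = TRUE)
    trace <- attr(p, "trace")
    lastQ <- -Inf
    for (s in seq_along(trace$Q)) {
      expect_equal(trace$Q[s],
                   graphModularity(g, trace$membership[[s]]),
                   tolerance = 1e-9)
      expect_gt(trace$Q[s], lastQ)       # accepted merges increase Q
      lastQ <- trace$Q[s]
    }
  }
})

test_that("greedy Q is near the exhaustive maximum on structured graphs", {
  # two 3-cliques with up to two inter-clique edges: community structure
  # above the agglomerative resolution limit
  set.seed(13)
  for (i in 1:25) {
    A <- twoCliquePlusCross(sample(0:2, 1))
    g <- graphFromAdjacency(A)
    qGreedy <- modularityQ(greedyModularityPartition(g))
    expect_gte(qGreedy, 0.95 * exhaustiveMaxQ(A) - 1e-12)
  }
})

test_that("greedy Q never exceeds the exhaustive maximum", {
  set.seed(14)
  tried <- 0
  while (tried < 25) {
    A <- randomGraphAdjacency(sample(4:6, 1), pEdge = 0.5)
    if (sum(A) == 0 || !isConnected(A)) next
    tried <- tried + 1
    qGreedy <- modularityQ(greedyModularityPartition(graphFromAdjacency(A)))
    expect_lte(qGreedy, exhaustiveMaxQ(A) + 1e-12)
  }
})

test_that("greedy merging matches or beats the reference CNM implementation", {
  skip_if_not_installed("igraph")
  # both are agglomerative CNM with different tie-breaking, so neither
  # dominates graph-by-graph; faithfulness means staying within a small
  # margin everywhere and winning or tying most of the time
  set.seed(15)
  tried <- 0; atLeast <- 0
  while (tried < 30) {
    A <- randomGraphAdjacency(sample(5:12, 1), pEdge = 0.4)
    if (sum(A) == 0) next
    tried <- tried + 1
    qMine <- modularityQ(greedyModularityPartition(graphFromAdjacency(A)))
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    qRef <- max(igraph::cluster_fast_greedy(ig)$modularity)
    expect_gte(qMine, qRef - 0.05)
    if (qMine >= qRef - 1e-9) atLeast <- atLeast + 1
  }
  expect_gte(atLeast / tried, 0.7)
})

test_that("isolated labels end as their own communities", {
  mols <- moleculesFromLabelSets(list(c("a", "b"), "z"))
  p <- greedyModularityPartition(buildOdorGraph(mols))
  memb <- communityOf(p)
  expect_equal(length(unique(memb[c("a", "b")])), 1L)
  expect_false(memb["z"] %in% memb[c("a", "b")])
})

test_that("majority-rule community assignment follows the strict 20% share", {
  labels <- c(paste0("one", 1:9), "two1", "f1", "f2", "f3", "f4", "f5")
  memb <- stats::setNames(c(rep(1L, 9), 2L, 1:5), labels)
  part <- new("OdorPartition", membership = memb, Q = NA_real_)

  nineToOne <- moleculesFromLabelSets(list(c(paste0("one", 1:9), "two1")))
  expect_equal(assignMoleculeCommunities(nineToOne, part)[[1]], 1L)

  even <- moleculesFromLabelSets(list(c("one1", "two1")))
  expect_equal(assignMoleculeCommunities(even, part)[[1]], c(1L, 2L))

  fiveWay <- moleculesFromLabelSets(list(c("f1", "f2", "f3", "f4", "f5")))
  expect_equal(assignMoleculeCommunities(fiveWay, part)[[1]], 1L)

  unknown <- moleculesFromLabelSets(list(c("one1", "mystery")))
  expect_warning(res <- assignMoleculeCommunities(unknown, part), "mystery")
  expect_equal(res[[1]], 1L)

  none <- moleculesFromLabelSets(list("mystery"))
  expect_warning(expect_warning(
    res2 <- assignMoleculeCommunities(none, part)))
  expect_equal(res2[[1]], integer(0))
})

test_that("assignment shares sum to one before thresholding", {
  set.seed(5)
  labels <- paste0("l", 1:12)
  memb <- stats::setNames(sample(1:4, 12, replace = TRUE), labels)
  for (i in 1:20) {
    ls <- sample(labels, sample(2:8, 1))
    shares <- table(memb[ls]) / length(ls)
    expect_equal(sum(shares), 1)
  }
})

test_that("partition and edge list CSV exports are readable", {
  g <- twoTriangles()
  p <- greedyModularityPartition(g)
  f1 <- withr::local_tempfile(fileext = ".csv")
  writePartition(p, f1)
  df <- utils::read.csv(f1)
  expect_equal(sort(df$odor_label), sort(names(communityOf(p))))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeEdgeList(g, f2)
  el <- utils::read.csv(f2)
  expect_equal(nrow(el), edgeCount(g))
  expect_true(all(el$weight >= 1))
})
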