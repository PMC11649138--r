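test_that("kernel weights follow the closed form on engineered geometry", {
  # place 3 points so that the pair (1,2) sits exactly at the median
  # squared distance; with mu = 0.5 its weight is exp(-2)
  x <- matrix(c(0, 1, 3,
                0, 0, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("d1", "d2")))
  # squared distances: 1 (a-b), 4 (b-c), 9 (a-c) -> median delta2 = 4
  g <- buildKnnGraph(OmicsMatrix(x, "x"), graphConfig(kNeighbors = 1, mu = 0.5))
  A <- adjacency(g)
  # b's nearest neighbour is a (rho2 = 1): w = exp(-1/(0.5*4)) = exp(-0.5);
  # a->b too, so the symmetrised weight is exp(-0.5)
  expect_equal(A["a", "b"], exp(-0.5), tolerance = 1e-12)
  # c's nearest is b (rho2 = 4 = delta2): exp(-2), halved by symmetrisation
  # because b does not select c
  expect_equal(A["b", "c"], exp(-2) / 2, tolerance = 1e-12)
  expect_equal(A["a", "c"], 0)  # not within anyone's k = 1
  expect_true(all(diag(A) == 0))
})

test_that("graph builder matches the brute-force oracle on random instances", {
  set.seed(77)
  maxDev <- 0
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    d <- sample(2:10, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("f%d", 1:d)))
    A <- adjacency(buildKnnGraph(OmicsMatrix(x, "x"),
                                 graphConfig(kNeighbors = k, mu = 0.5)))
    B <- bruteKnnGraph(x, k, 0.5)
    maxDev <- max(maxDev, max(abs(A - B)))
  }
  expect_lt(maxDev, 1e-12)
})

test_that("graph construction is equivariant under sample permutation", {
  set.seed(5)
  m <- makeOmics(n = 12, d = 4)
  g <- buildKnnGraph(m, graphConfig(kNeighbors = 3))
  perm <- sample(nSamples(m))
  mp <- OmicsMatrix(assayValues(m)[perm, ], omicsName(m))
  gp <- buildKnnGraph(mp, graphConfig(kNeighbors = 3))
  expect_equal(adjacency(gp), adjacency(g)[perm, perm], tolerance = 1e-14)
})

test_that("degenerate geometry is rejected", {
  x <- matrix(1, 4, 2, dimnames = list(letters[1:4], c("f1", "f2")))
  expect_error(buildKnnGraph(OmicsMatrix(x, "x"), graphConfig(kNeighbors = 2)),
               "degenerate geometry")
  expect_error(buildKnnGraph(makeOmics(n = 3), graphConfig(kNeighbors = 3)),
               "kNeighbors")
})

test_that("graph fusion is the elementwise mean", {
  set.seed(21)
  gs <- lapply(1:4, function(i) buildKnnGraph(makeOmics(n = 10, d = 3,
                                                        seed = i),
                                              graphConfig(kNeighbors = 2)))
  fused <- fuseGraphs(gs)
  oracle <- (adjacency(gs[[1]]) + adjacency(gs[[2]]) + adjacency(gs[[3]]) +
               adjacency(gs[[4]])) / 4
  expect_lt(max(abs(adjacency(fused) - oracle)), 1e-12)
  expect_equal(adjacency(fuseGraphs(list(gs[[1]], gs[[1]], gs[[1]], gs[[1]]))),
               adjacency(gs[[1]]))
  zero <- new("SampleGraph", sampleIds = sampleIds(gs[[1]]),
              adjacency = adjacency(gs[[1]]) * 0)
  expect_equal(adjacency(fuseGraphs(list(gs[[1]], gs[[1]], gs[[1]], zero))),
               0.75 * adjacency(gs[[1]]), tolerance = 1e-14)
  bad <- new("SampleGraph", sampleIds = rev(sampleIds(gs[[1]])),
             adjacency = adjacency(gs[[1]]))
  expect_error(fuseGraphs(list(gs[[1]], bad)), "mismatched")
})

test_that("normalisation matches hand-computed operator on a path graph", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A["a", "b"] <- A["b", "a"] <- 1
  A["b", "c"] <- A["c", "b"] <- 1
  ng <- normalizeAdjacency(new("SampleGraph", sampleIds = c("a", "b", "c"),
                               adjacency = A))
  M <- convMatrix(ng)
  # degrees with self-loops: (2, 3, 2)
  expect_equal(M["a", "a"], 1 / 2, tolerance = 1e-12)
  expect_equal(M["a", "b"], 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(M["b", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(M["a", "c"], 0)

  # all-zero adjacency: isolated nodes normalise to the identity
  ng0 <- normalizeAdjacency(new("SampleGraph", sampleIds = c("a", "b", "c"),
                                adjacency = A * 0))
  expect_equal(convMatrix(ng0), diag(3), ignore_attr = TRUE)
})

test_that("normalised operators are symmetric with spectrum in [-1, 1]", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    m <- makeOmics(n = n, d = 4, seed = 100 + rep)
    ng <- normalizeAdjacency(buildKnnGraph(m, graphConfig(kNeighbors = 2)))
    M <- convMatrix(ng)
    expect_lt(max(abs(M - t(M))), 1e-12)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
})

test_that("edge lists serialise nonzero upper-triangle entries", {
  g <- buildKnnGraph(makeOmics(n = 8, d = 3, seed = 4),
                     graphConfig(kNeighbors = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(g, f)
  df <- read.delim(f)
  A <- adjacency(g)
  expect_equal(nrow(df), sum(A[upper.tri(A)] > 0))
  expect_equal(df$weight[1], A[df$i[1], df$j[1]])
})
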