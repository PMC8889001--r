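test_that("union-find components match the graph oracle", {
  cc <- connectedComponents(5, rbind(c(1, 2), c(2, 3)))
  expect_equal(clusterLabels(cc), c(1L, 1L, 1L, 4L, 5L))
  expect_equal(sort(isolatedPoints(cc)), c(4L, 5L))

  empty <- connectedComponents(3, matrix(integer(0), 0, 2))
  expect_equal(clusterLabels(empty), 1:3)
  expect_length(isolatedPoints(empty), 3L)

  expect_error(connectedComponents(3, rbind(c(1, 4))), "out of range")

  for (seed in 1:5) {
    set.seed(seed)
    n <- 200L
    edges <- cbind(sample(n, 150, TRUE), sample(n, 150, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    expect_identical(clusterLabels(connectedComponents(n, edges)),
                     igraphPartition(n, edges))
  }
})

test_that("coding selection follows dimension and honours overrides", {
  expect_equal(selectCoding(1e6, 2), "sd")
  expect_equal(selectCoding(1e4, 2000), "dm")
  expect_equal(selectCoding(100, 2000, override = "dm"), "dm")
  expect_error(selectCoding(100, 2000, override = "sd"), "DM")
})

test_that("hierarchy links children to the coarser cluster holding them", {
  mk <- function(labels, scale) {
    sizes <- table(labels)
    szInt <- as.integer(sizes); names(szInt) <- names(sizes)
    new("ScaleClustering", scale = scale, labels = as.integer(labels),
        sizes = szInt, isolated = as.integer(names(sizes))[szInt == 1L])
  }
  h <- buildHierarchy(list(mk(rep(1L, 6), 1L),
                           mk(c(1, 1, 1, 4, 4, 4), 2L)))
  nodes <- h@nodes
  expect_equal(nodes$parent[nodes$scale == 2], c(1L, 1L))
  expect_equal(h@repaired, 0L)

  single <- buildHierarchy(list(mk(c(1, 1, 3), 1L)))
  expect_true(all(is.na(single@nodes$parent)))

  expect_error(buildHierarchy(list(mk(rep(1L, 6), 1L), mk(rep(1L, 5), 2L))),
               "inconsistent")
})

test_that("a single blob is one cluster at the grossest scale", {
  set.seed(2)
  X <- cbind(rnorm(150), rnorm(150))
  res <- runWFC(X, lambda = 1, coding = "sd", seed = 1)
  expect_length(clusterSizes(scaleClustering(res, 1)), 1L)
  expect_equal(sum(clusterSizes(scaleClustering(res, nScales(res)))), 150L)
})

test_that("DM partitions refine exactly across scales with no repairs", {
  pb <- makePlantedBinary(seed = 21)
  for (cfg in list(list(), list(bruteCutoff = 0L))) {
    res <- runWFC(pb$codes, lambda = 0.25, config = cfg, seed = 2)
    expect_equal(repairedParents(res), 0L)
    for (s in seq_len(nScales(res) - 1L)) {
      coarse <- clusterLabels(res, s)
      fine <- clusterLabels(res, s + 1L)
      expect_true(all(tapply(coarse, fine,
                             function(v) length(unique(v))) == 1L))
    }
    # each fine cluster's members are a subset of the parent's
    nodes <- hierarchyTable(res)
    lastS <- nScales(res)
    for (id in nodes$id[nodes$scale == lastS][1:3]) {
      par <- nodes$parent[nodes$scale == lastS & nodes$id == id]
      members <- which(clusterLabels(res, lastS) == id)
      expect_true(all(clusterLabels(res, lastS - 1L)[members] == par))
    }
  }
})

test_that("identical inputs and seed give identical results", {
  pb <- makePlantedBinary(nClusters = 4, perCluster = 60, D = 300,
                          coreSize = 25, seed = 31)
  r1 <- runWFC(pb$codes, lambda = 0.25, seed = 5)
  r2 <- runWFC(pb$codes, lambda = 0.25, seed = 5)
  expect_identical(lapply(seq_len(nScales(r1)), clusterLabels, x = r1),
                   lapply(seq_len(nScales(r2)), clusterLabels, x = r2))
  expect_identical(hierarchyTable(r1), hierarchyTable(r2))
})

test_that("smaller lambda yields at least as many scales", {
  set.seed(4)
  X <- cbind(runif(250, 0, 5), runif(250, 0, 5))
  sFine <- nScales(runWFC(X, lambda = 0.25, coding = "sd", seed = 1))
  sCoarse <- nScales(runWFC(X, lambda = 1, coding = "sd", seed = 1))
  expect_gte(sFine, sCoarse)
})

test_that("precomputed binary codes force DM mode", {
  pb <- makePlantedBinary(nClusters = 2, perCluster = 20, D = 100,
                          coreSize = 10, seed = 8)
  res <- runWFC(pb$codes, lambda = 0.5, seed = 1)
  expect_equal(res@coding, "dm")
  expect_error(runWFC(pb$codes, lambda = 0.5, coding = "sd", seed = 1),
               "DM")
})
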