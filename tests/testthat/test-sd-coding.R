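test_that("Chebyshev distance is the max componentwise difference", {
  expect_equal(chebyshevDist(c(0, 0), c(3, 4)), 4)
  expect_equal(chebyshevDist(c(1, 1), c(1, 1)), 0)
  expect_equal(chebyshevDist(c(-1, 2, 0), c(2, 2, -5)), 5)
  expect_error(chebyshevDist(c(1, 2), c(1, 2, 3)), "dimension mismatch")
})

test_that("grid encoding uses half-open cells anchored at the data minima", {
  code <- sdEncode(cbind(c(0, 0.9, 2.1)), delta = 1)
  expect_equal(as.vector(code@cells), c(0, 0, 2))

  code2 <- sdEncode(rbind(c(0.5, 0.5), c(1.5, 0.4)), delta = 1)
  expect_equal(unname(code2@cells), rbind(c(0, 0), c(1, 0)))
  expect_equal(max(abs(code2@cells[1, ] - code2@cells[2, ])), 1)

  expect_error(sdEncode(cbind(1:3), delta = 0), "delta")
})

test_that("a cell side above the diameter links everything", {
  set.seed(1)
  X <- matrix(runif(100), 50, 2)
  diam <- max(apply(X, 2, function(v) diff(range(v))))
  cc <- connectedComponents(50, sdLink(sdEncode(X, diam * 1.01)))
  expect_length(clusterSizes(cc), 1L)
})

test_that("adjacency linking matches the brute-force predicate oracle", {
  configs <- expand.grid(n = c(150, 300), d = 1:3, rep = 1:2)
  for (i in seq_len(nrow(configs))) {
    n <- configs$n[i]; d <- configs$d[i]
    set.seed(1000 + i)
    X <- matrix(runif(n * d), n, d)
    delta <- runif(1, 0.02, 0.3)
    got <- clusterLabels(connectedComponents(n, sdLink(sdEncode(X, delta))))
    expect_identical(got, bruteSdPartition(X, delta),
                     label = sprintf("n=%d d=%d delta=%.3f", n, d, delta))
  }
})

test_that("grid adjacency sandwiches the Chebyshev distance", {
  set.seed(42)
  X <- matrix(runif(400), 200, 2)
  delta <- 0.15
  code <- sdEncode(X, delta)
  D <- as.matrix(dist(X, method = "maximum"))
  Dc <- as.matrix(dist(code@cells, method = "maximum"))
  linked <- Dc <= 1
  expect_true(all(D[linked & upper.tri(D)] < 2 * delta))
  expect_true(all(linked[D < delta]))
})

test_that("partitions are invariant to point order and keep duplicates together", {
  set.seed(7)
  X <- matrix(rnorm(240), 120, 2)
  X[7, ] <- X[101, ]                       # plant a duplicate pair
  labs <- clusterLabels(connectedComponents(120, sdLink(sdEncode(X, 0.2))))
  perm <- sample(120)
  Xp <- X[perm, ]
  labsP <- clusterLabels(connectedComponents(120, sdLink(sdEncode(Xp, 0.2))))
  # same partition after undoing the permutation
  expect_identical(canonLabels(labsP[order(perm)]), canonLabels(labs))
  for (delta in c(1e-6, 0.01, 1)) {
    l <- clusterLabels(connectedComponents(120, sdLink(sdEncode(X, delta))))
    expect_identical(l[7], l[101])
  }
})

test_that("splice codes of coarser scales are prefixes under halving", {
  set.seed(3)
  X <- matrix(runif(60, 0, 8), 30, 2)
  origin <- apply(X, 2, min)
  fine <- sdSpliceCodes(sdEncode(X, 1, origin = origin), bits = 3)
  coarse <- sdSpliceCodes(sdEncode(X, 2, origin = origin), bits = 2)
  expect_true(all(substr(fine, 1, 4) == coarse))
})

test_that("high dimension is refused with advice to use DM", {
  X <- matrix(runif(20 * 13), 20, 13)
  expect_error(sdLink(sdEncode(X, 0.5)), "DM")
})
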