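test_that("marker encoding rules match their definitions", {
  expect_equal(markerSets(dmEncode(rbind(c(0, 2.5, 0, 1))))[[1]], c(2L, 4L))
  expect_equal(markerSets(dmEncode(rbind(c(0.1, -3, 0.2)), mode = "top_m",
                                   m = 1))[[1]], 2L)
  # binned: d = 1, range [0, 1], x = 0.75 -> bin 1 of dimension 1 (marker 2)
  bc <- dmEncode(cbind(c(0, 0.75, 1)), mode = "binned", bins = 2)
  expect_equal(markerSets(bc), list(1L, 2L, 2L))
  expect_equal(codeLength(bc), 2L)

  expect_error(dmEncode(rbind(c(1, 2), c(0, 0))), "point")
})

test_that("Jaccard similarity is H(AND)/H(OR)", {
  expect_equal(jaccardSim(c(1, 3, 4), c(1, 3, 4)), 1)
  expect_equal(jaccardSim(c(1, 3), c(2, 4)), 0)
  expect_equal(jaccardSim(c(1, 3, 4), c(1, 4, 5)), 0.5)
  expect_error(jaccardSim(integer(0), integer(0)), "empty")

  set.seed(5)
  for (i in 1:25) {
    a <- sample(40, sample(1:15, 1))
    b <- sample(40, sample(1:15, 1))
    expect_equal(jaccardSim(a, b), bruteJaccard(a, b))
    expect_equal(jaccardSim(a, b), jaccardSim(b, a))
    expect_gte(jaccardSim(a, b), 0)
    expect_lte(jaccardSim(a, b), 1)
    expect_equal(jaccardSim(a, b) == 1, setequal(a, b))
  }
})

test_that("MinHash signatures are deterministic and concentrate on Jaccard", {
  codes <- BinaryCodes(list(c(1, 5, 9), c(1, 5, 9), c(2, 6)), D = 10)
  s1 <- minhashSignatures(codes, k = 32, seed = 4)
  s2 <- minhashSignatures(codes, k = 32, seed = 4)
  expect_identical(s1@signatures, s2@signatures)
  expect_identical(s1@signatures[, 1], s1@signatures[, 2])
  expect_error(minhashSignatures(codes, k = 8), "at least 16")

  # estimator concentration: agreement within 3 binomial sd of J for >=95%
  set.seed(11)
  k <- 256L
  hits <- 0L
  npairs <- 60L
  pairs <- lapply(seq_len(npairs), function(i) {
    core <- sample(200, 40)
    list(a = c(core, sample(201:400, 15)), b = c(core, sample(401:600, 10)))
  })
  codes <- BinaryCodes(c(lapply(pairs, `[[`, "a"), lapply(pairs, `[[`, "b")),
                       D = 600)
  sig <- minhashSignatures(codes, k = k, seed = 2)@signatures
  for (i in seq_len(npairs)) {
    Jtrue <- jaccardSim(pairs[[i]]$a, pairs[[i]]$b)
    agree <- mean(sig[, i] == sig[, npairs + i])
    if (abs(agree - Jtrue) <= 3 * sqrt(Jtrue * (1 - Jtrue) / k))
      hits <- hits + 1L
  }
  expect_gte(hits / npairs, 0.95)
})

test_that("the MinHash estimator is unbiased across hash families", {
  a <- c(1:20, 30:39)
  b <- c(1:20, 50:54)
  Jtrue <- jaccardSim(a, b)  # 20/35
  codes <- BinaryCodes(list(a, b), D = 60)
  agree <- vapply(1:50, function(seed) {
    sig <- minhashSignatures(codes, k = 256, seed = seed)@signatures
    mean(sig[, 1] == sig[, 2])
  }, numeric(1))
  expect_lt(abs(mean(agree) - Jtrue), 0.02)
})

test_that("band choice respects the S-curve midpoint constraint", {
  br <- chooseBands(256, 0.5)
  expect_equal(br[["b"]] * br[["r"]], 256)
  expect_lte((1 / br[["b"]])^(1 / br[["r"]]), 0.5)
  # exhaustive check: no admissible factorization sits closer to t
  divs <- which(256 %% seq_len(256) == 0)   # candidate r values
  mids <- (1 / (256 / divs))^(1 / divs)
  expect_equal((1 / br[["b"]])^(1 / br[["r"]]), max(mids[mids <= 0.5]))

  expect_equal(unname(chooseBands(16, 1.0)), c(1, 16))
  expect_error(chooseBands(4, 0.01), "larger k")
  expect_error(chooseBands(16, 0), "in \\(0, 1\\]")
})

test_that("thresholded pair retrieval has no false positives and nests", {
  pb <- makePlantedBinary(nClusters = 3, perCluster = 40, D = 200,
                          coreSize = 20, flip = 0.15, background = 0.02,
                          seed = 9)
  idx <- minhashSignatures(pb$codes, k = 256, seed = 9)
  J <- wfclust:::jaccardMatrix(pb$codes)
  prev <- NULL
  for (t in c(0.15, 0.3, 0.5, 0.8)) {
    lp <- lshPairs(idx, pb$codes, t, bruteCutoff = 0L)
    if (nrow(lp)) expect_true(all(J[lp] >= t - 1e-12))
    if (!is.null(prev) && nrow(lp)) {
      keyNow <- (lp[, 1] - 1) * 1000 + lp[, 2]
      expect_true(all(keyNow %in% prev))     # edges nest as t grows
    }
    prev <- (lp[, 1] - 1) * 1000 + lp[, 2]
  }
  # brute-force mode equals the explicit-loop oracle
  small <- BinaryCodes(markerSets(pb$codes)[1:40], D = 200)
  bi <- minhashSignatures(small, k = 256, seed = 1)
  got <- lshPairs(bi, small, 0.4, bruteCutoff = 1000L)
  expect_equal(unname(got), unname(bruteJaccardPairs(markerSets(small), 0.4)))
})

test_that("identical codes are always retrieved; unverified output may overshoot", {
  codes <- BinaryCodes(list(c(1, 2, 3), c(1, 2, 3), c(7, 8)), D = 10)
  idx <- minhashSignatures(codes, k = 64, seed = 2)
  lp <- lshPairs(idx, codes, 0.9, bruteCutoff = 0L)
  expect_equal(unname(lp), cbind(1L, 2L))

  pb <- makePlantedBinary(nClusters = 2, perCluster = 30, D = 100,
                          coreSize = 15, flip = 0.2, background = 0.05,
                          seed = 3)
  idx <- minhashSignatures(pb$codes, k = 256, seed = 3)
  ver <- lshPairs(idx, pb$codes, 0.5, bruteCutoff = 0L)
  raw <- lshPairs(idx, pb$codes, 0.5, exactVerify = FALSE, bruteCutoff = 0L)
  keyV <- (ver[, 1] - 1) * 1000 + ver[, 2]
  keyR <- (raw[, 1] - 1) * 1000 + raw[, 2]
  expect_true(all(keyV %in% keyR))
  expect_gte(nrow(raw), nrow(ver))
})
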