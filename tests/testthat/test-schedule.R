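test_that("SD similarity bounds follow reciprocal Chebyshev distances", {
  b <- estimateSimilarityBounds(rbind(c(0, 0), c(3, 4)), "sd")
  expect_equal(b$simMin, 1 / 4)
  expect_equal(b$simMax, 1 / 4)

  expect_error(estimateSimilarityBounds(rbind(c(0, 0), c(0, 0)), "sd"),
               "zero similarity range")
  expect_error(estimateSimilarityBounds(matrix(1, 1, 2), "sd"),
               "at least two")
})

test_that("DM similarity bounds are the extreme nonzero Jaccard values", {
  codes <- BinaryCodes(list(c(1, 3, 4), c(1, 4, 5), 5), D = 5)
  b <- estimateSimilarityBounds(mode = "dm", codes = codes)
  expect_equal(b$simMax, 1 / 2)   # {1,3,4} vs {1,4,5}
  expect_equal(b$simMin, 1 / 3)   # {1,4,5} vs {5}; the zero pair is excluded

  # clamp: a near-disjoint pair cannot push simMin below 1/(2D)
  far <- BinaryCodes(list(1:50, c(50, 101:149)), D = 200)
  bf <- estimateSimilarityBounds(mode = "dm", codes = far)
  expect_gte(bf$simMin, 1 / 400)
})

test_that("exact-mode bounds match an all-pairs oracle on small data", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(2 * 80), 80, 2)
    b <- estimateSimilarityBounds(X, "sd", sampleSize = 200)
    D <- as.matrix(dist(X, method = "maximum"))
    expect_equal(b$simMin, 1 / max(D))
    expect_equal(b$simMax, 1 / min(D[upper.tri(D) & D > 0]))
  }
})

test_that("the scale count follows the floor closed form", {
  expect_identical(sEnd(buildSchedule(1, 2^25, 1)), 25L)
  expect_identical(sEnd(buildSchedule(0.1, 0.15, 1)), 1L)  # clamped floor 0
  expect_identical(sEnd(buildSchedule(1, 100, 0.05)),
                   as.integer(floor(log(100) / log(1.05))))  # 94
  expect_error(buildSchedule(1, 2, 0), "lambda")
  expect_error(buildSchedule(0, 2, 1), "simMin")
})

test_that("thresholds follow each policy and anchor at simMin", {
  expect_equal(thresholdAt(buildSchedule(0.25, 10, 1), 3), 1.0)
  expect_equal(thresholdAt(buildSchedule(1, 5, 0.5), 1), 1.0)
  hyp <- buildSchedule(1, 2^25, 1, policy = "hyper_exponential")
  expect_equal(thresholdAt(hyp, 4), 512)    # (1+1)^((4-1)^2)
  expect_error(thresholdAt(hyp, sEnd(hyp) + 1L), "out of range")

  # geometric ratio is exactly 1 + lambda
  s <- buildSchedule(0.037, 812, 0.3)
  r <- s@thresholds[-1] / s@thresholds[-sEnd(s)]
  expect_true(all(abs(r - 1.3) < 1e-12 * 1.3))
  expect_equal(s@thresholds[1], 0.037)

  lin <- buildSchedule(1, 3, 0.5, policy = "linear")
  expect_equal(thresholds(lin), c(1, 1.5, 2, 2.5, 3))
})

test_that("iterative JND updates agree with the closed form", {
  s <- buildSchedule(0.01, 250, 0.17)
  th <- 0.01
  for (i in seq_len(sEnd(s))) {
    expect_equal(thresholdAt(s, i), th, tolerance = 1e-9)
    th <- th * 1.17
  }
})

test_that("s_end is non-increasing in lambda and overshoot is bounded", {
  grid <- c(0.05, 0.1, 0.25, 0.5, 1)
  se <- vapply(grid, function(l) sEnd(buildSchedule(0.02, 37, l)), integer(1))
  expect_true(all(diff(se) <= 0))
  for (pol in c("weber_fechner", "hyper_exponential", "linear")) {
    s <- buildSchedule(0.02, 37, 0.4, policy = pol)
    expect_lte(thresholdAt(s, sEnd(s)), 37 * 1.4 + 1e-9)
    expect_true(all(diff(thresholds(s)) > 0))
  }
})

test_that("schedules serialize to JSON and back", {
  s <- buildSchedule(0.5, 64, 1)
  path <- withr::local_tempfile(fileext = ".json")
  scheduleToJSON(s, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$s_end, 7)
  expect_equal(back$thresholds, thresholds(s))
  expect_equal(back$lambda, 1)
})
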