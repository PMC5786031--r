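test_that("skip penalty combines the minimum and spread of row minima", {
  expect_equal(skip_penalty(matrix(c(0, 1, 1, 0), 2)), 0)
  expect_equal(skip_penalty(matrix(3, 4, 5)), 3)
  expect_equal(skip_penalty(matrix(c(2, 5, 1), 1)), 1)
  # row minima (1, 3): min 1 + population sd 1
  expect_equal(skip_penalty(rbind(c(1, 9), c(9, 3))), 2)
})

test_that("a diagonal-favoring matrix yields the identity path at zero cost", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  p <- osb_match(d, 0.5)
  expect_equal(p$pairs, cbind(1:5, 1:5))
  expect_equal(p$cost, 0)
})

test_that("dynamic programming agrees with exhaustive enumeration", {
  set.seed(42)
  for (i in 1:100) {
    m <- sample(1:8, 1); p <- sample(1:8, 1)
    delta <- matrix(runif(m * p, 0, 5), m, p)
    xi <- runif(1, 0, 2)
    a <- osb_match(delta, xi)
    b <- osb_enumerate(delta, xi)
    expect_equal(a$cost, b$cost, tolerance = 1e-12)
    expect_equal(nrow(a$pairs), nrow(b$pairs))
  }
})

test_that("an element with uniformly huge dissimilarity is skipped", {
  set.seed(8)
  delta <- matrix(runif(42, 0, 0.2), 6, 7)
  delta[3, ] <- 50
  p <- osb_match(delta, 0.05)
  expect_false(3 %in% p$pairs[, 1])
  expect_equal(osb_enumerate(delta, 0.05)$cost, p$cost, tolerance = 1e-12)
})

test_that("zero penalty with positive dissimilarities selects one best pair", {
  set.seed(9)
  delta <- matrix(runif(30, 0.1, 2), 5, 6)
  p <- osb_match(delta, 0)
  expect_equal(nrow(p$pairs), 1)
  expect_equal(p$cost, min(delta))
})

test_that("a huge penalty forbids interior skips", {
  set.seed(10)
  delta <- matrix(runif(36, 0, 1), 6, 6)
  p <- osb_match(delta, 1e6)
  k <- p$pairs[, 1]; l <- p$pairs[, 2]
  expect_true(all(diff(k) == 1))
  expect_true(all(diff(l) == 1))
  expect_equal(nrow(p$pairs), 6)
})

test_that("paths are strictly monotone and empty inputs give empty paths", {
  set.seed(12)
  for (i in 1:20) {
    delta <- matrix(runif(9 * 11), 9, 11)
    p <- osb_match(delta, runif(1, 0, 1))
    if (nrow(p$pairs) > 1) {
      expect_true(all(diff(p$pairs[, 1]) > 0))
      expect_true(all(diff(p$pairs[, 2]) > 0))
    }
  }
  p0 <- osb_match(matrix(numeric(0), 0, 0), 1)
  expect_equal(nrow(p0$pairs), 0)
})

test_that("cost ties break toward the path with more pairs", {
  delta <- matrix(0, 4, 4)
  p <- osb_match(delta, 1)
  expect_equal(nrow(p$pairs), 4)     # the all-zero matrix admits 1..4 pairs
})

test_that("dynamic time warping aligns and stays monotone many-to-many", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  p <- dtw_match(d)
  expect_equal(p$pairs, cbind(1:4, 1:4))
  set.seed(13)
  d2 <- matrix(runif(40), 5, 8)
  p2 <- dtw_match(d2)
  expect_true(all(diff(p2$pairs[, 1]) >= 0))
  expect_true(all(diff(p2$pairs[, 2]) >= 0))
  expect_equal(p2$pairs[1, ], c(1, 1))
  expect_equal(p2$pairs[nrow(p2$pairs), ], c(5, 8))
  # DTW covers both sequences entirely
  expect_gte(nrow(p2$pairs), 8)
})
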