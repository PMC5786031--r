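test_that("vesselness vanishes on structureless images and finds tube axes", {
  expect_equal(max(vesselness(matrix(0.5, 64, 64))), 0)
  # dark horizontal tube of width ~4 px on a bright background
  img <- matrix(1, 120, 120)
  for (r in 1:120) img[r, ] <- 0.2 + 0.8 * pmin(1, pmax(0, abs(r - 60) - 1.5))
  V <- vesselness(img)
  amax <- apply(V[, 20:100], 2, which.max)
  expect_true(all(abs(amax - 60) <= 1))
  expect_lt(max(abs(vesselness(img + 0.1) - V)), 1e-12)
  expect_error(vesselness(array(0, c(4, 4, 2))), "2D")
})

test_that("fast-marching arrival times approximate Euclidean distance", {
  Tm <- coroxr:::cx_fmm(matrix(1, 200, 200), 100, 100)
  rr <- row(Tm) - 100; cc <- col(Tm) - 100
  dv <- sqrt(rr^2 + cc^2)
  expect_lt(max(abs(Tm - dv) / pmax(dv, 1)), 0.02)
})

test_that("tracked paths stay inside a bright channel and handle seeds", {
  maze <- matrix(1e-3, 100, 100)
  maze[48:52, 10:80] <- 1
  maze[48:90, 76:80] <- 1
  paths <- track_centerline(maze, c(10, 50), list(c(78, 88)))
  p <- paths[[1]]
  expect_equal(mean(maze[cbind(p[, 2], p[, 1])] > 0.5), 1)
  expect_equal(p[1, ], c(10, 50))
  # outlet equal to the inlet degenerates to a single point
  p0 <- track_centerline(maze, c(10, 50), list(c(10, 50)))[[1]]
  expect_equal(nrow(p0), 1)
})

test_that("tracked tube centerline deviates less than 1 px RMS from truth", {
  img <- matrix(1, 80, 160)
  for (r in 1:80) img[r, ] <- 0.2 + 0.8 * pmin(1, pmax(0, abs(r - 40) - 3))
  sp <- 1e-3 + vesselness(img)
  p <- track_centerline(sp, c(8, 40), list(c(152, 40)))[[1]]
  mid <- p[p[, 1] > 15 & p[, 1] < 145, ]
  expect_lt(sqrt(mean((mid[, 2] - 40)^2)), 1)
})

test_that("overlapping paths decompose into branches at divergence points", {
  stem <- cbind(1:50, rep(10, 50))
  p1 <- rbind(stem, cbind(50 + 1:30, 10 + 1:30))
  p2 <- rbind(stem, cbind(50 + 1:30, 10 - 1:30))
  tr <- decompose_tree(list(p1, p2))
  expect_equal(length(tr$branches), 3)
  expect_equal(length(tr$bifurcations), 1)
  expect_equal(tr$bifurcations[[1]]$point, c(50, 10))
  # a single path is a single branch
  tr1 <- decompose_tree(list(p1))
  expect_equal(length(tr1$branches), 1)
  expect_equal(length(tr1$bifurcations), 0)
  # nested divergences
  a <- rbind(stem[1:40, ], cbind(40 + 1:30, 10 + 1:30))
  b <- rbind(stem[1:40, ], cbind(40 + 1:15, 10 + 1:15), cbind(55 + 1:15, 25 - 0:14))
  c2 <- rbind(stem[1:40, ], cbind(40 + 1:30, 10 - 1:30))
  tr3 <- decompose_tree(list(a, b, c2))
  expect_equal(length(tr3$branches), 5)
  expect_equal(length(tr3$bifurcations), 2)
  # the shared stem is a single branch rooted at the inlet
  expect_equal(nrow(tr3$branches[[1]]), 40)
  expect_equal(tr3$inlet, c(1, 10))
  expect_true(is.na(tr3$parent[1]))
})

test_that("borders of a straight synthetic vessel sit at the true half-width", {
  img <- matrix(1, 120, 120)
  for (cl in 1:120)
    img[, cl] <- 0.2 + 0.8 * pmin(1, pmax(0, abs(cl - 60) - 6 + 0.5))
  ctr <- cbind(rep(60, 100), seq(11, 110))
  bp <- detect_borders(img, ctr)
  err_l <- abs(abs(bp$left[, 1] - 60) - 6)
  err_r <- abs(abs(bp$right[, 1] - 60) - 6)
  expect_lt(mean(err_l), 1)
  expect_lt(mean(err_r), 1)
  # borders never touch the centerline column
  expect_true(all(bp$left[, 1] != 60))
  expect_true(all(bp$right[, 1] != 60))
  # and lie on opposite sides
  expect_true(all(bp$left[, 1] < 60) || all(bp$left[, 1] > 60))
  expect_true(sign(mean(bp$left[, 1] - 60)) != sign(mean(bp$right[, 1] - 60)))
})

test_that("the border half-width profile recovers an imposed narrowing", {
  img <- matrix(1, 120, 160)
  hw <- 8 - 4 * exp(-((seq_len(160) - 80) / 12)^2 / 2)   # stenosis at col 80
  for (cl in 1:160)
    img[, cl] <- 0.2 + 0.8 * pmin(1, pmax(0, abs(seq_len(120) - 60) - hw[cl] + 0.5))
  ctr <- cbind(seq(11, 150), rep(60, 140))
  bp <- detect_borders(img, ctr)
  width <- function(b) {
    o <- order(b[, 1])
    approx(b[o, 1], abs(b[o, 2] - 60), xout = 40:120)$y
  }
  prof <- (width(bp$left) + width(bp$right)) / 2
  # discrete borders quantize the width, so the minimum is a plateau; its
  # center locates the stenosis
  at_min <- (40:120)[prof <= min(prof) + 0.25]
  expect_lt(abs(mean(range(at_min)) - 80), 2)
})
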