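test_that("the recursive basis matches an independent B-spline implementation", {
  kn <- c(0, 0, 0, 0, 0.3, 0.6, 1, 1, 1, 1)
  t <- seq(0, 1, length.out = 57)
  B <- coroxr:::bspline_basis(t, kn, 4)
  ref <- splines::splineDesign(kn, t, ord = 4, outer.ok = TRUE)
  expect_lt(max(abs(B - ref)), 1e-12)
  Bd <- coroxr:::bspline_basis(t, kn, 4, deriv = 1)
  refd <- splines::splineDesign(kn, t, ord = 4, derivs = rep(1, length(t)),
                                outer.ok = TRUE)
  expect_lt(max(abs(Bd - refd)), 1e-8)
})

test_that("the basis partitions unity over the domain", {
  set.seed(2)
  kn <- c(0, 0, 0, 0, sort(runif(5)), 1, 1, 1, 1)
  t <- runif(100)
  B <- coroxr:::bspline_basis(t, kn, 4)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
})

test_that("fitting reproduces straight lines exactly", {
  pts <- cbind(seq(0, 10, length.out = 20), 0, 0)
  cv <- fit_bspline(pts, k = 4, n_ctrl = 8)
  ev <- eval_bspline(cv, seq(0, 1, length.out = 200))
  expect_lt(max(abs(ev[, 2:3])), 1e-9)
  expect_equal(bspline_length(cv), 10, tolerance = 1e-9)
})

test_that("a smoothing fit tracks a helix to sub-0.01 mm", {
  s <- seq(0, 4 * pi, length.out = 50)
  pts <- cbind(2 * cos(s), 2 * sin(s), 5 * s / (2 * pi))
  cv <- fit_bspline(pts, k = 4, n_ctrl = 25)
  fitpts <- eval_bspline(cv, coroxr:::chord_params(pts))
  expect_lt(sqrt(mean(rowSums((fitpts - pts)^2))), 0.01)
})

test_that("coincident consecutive points are deduplicated with a warning", {
  pts <- cbind(c(0, 1, 1, 2, 3), 0, 0)
  expect_warning(cv <- fit_bspline(pts, k = 4), "coincident")
  expect_equal(nrow(cv$control), 4)
})

test_that("Frenet frames of a planar circle have a constant binormal", {
  th <- seq(0, 1.8 * pi, length.out = 80)
  cc <- fit_bspline(cbind(10 * cos(th), 10 * sin(th), 0), 4, 40)
  fr <- frenet_frames(cc, seq(0.05, 0.95, length.out = 25))
  expect_lt(max(abs(abs(fr$B[, 3]) - 1)), 1e-6)
  expect_equal(max(abs(fr$B[, 1:2])), 0, tolerance = 1e-6)
})

test_that("straight segments fall back to rotation-minimizing frames", {
  cv <- fit_bspline(cbind(seq(0, 10, length.out = 12), 0, 0), 4, 6)
  fr <- frenet_frames(cv, seq(0, 1, length.out = 10))
  expect_equal(fr$T, matrix(rep(c(1, 0, 0), each = 10), 10), tolerance = 1e-9)
  for (i in 1:10) {
    G <- rbind(fr$T[i, ], fr$N[i, ], fr$B[i, ])
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-9)
  }
  # no flips between consecutive frames
  expect_true(all(rowSums(fr$N[-1, ] * fr$N[-10, ]) > 0.99))
})

test_that("helix frames match the analytic Frenet trihedron within 1 degree", {
  s <- seq(0, 4 * pi, length.out = 60)
  pts <- cbind(2 * cos(s), 2 * sin(s), 5 * s / (2 * pi))
  cv <- fit_bspline(pts, k = 4, n_ctrl = 45)
  ts <- seq(0.1, 0.9, length.out = 15)
  fr <- frenet_frames(cv, ts)
  sA <- approx(coroxr:::chord_params(pts), s, xout = ts)$y
  c_ <- 5 / (2 * pi); den <- sqrt(4 + c_^2)
  Tan <- cbind(-2 * sin(sA), 2 * cos(sA), c_) / den
  Nan <- cbind(-cos(sA), -sin(sA), 0)
  angT <- acos(pmin(1, rowSums(fr$T * Tan))) * 180 / pi
  angN <- acos(pmin(1, abs(rowSums(fr$N * Nan)))) * 180 / pi
  expect_lt(max(angT), 1)
  expect_lt(max(angN), 1)
})
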