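test_that("circle fits are exact on noise-free points", {
  th <- c(0, 90, 180, 270) * pi / 180
  f <- fit_cross_section(cbind(2 * cos(th), 2 * sin(th)), "circle")
  expect_equal(f$radius, 2, tolerance = 1e-9)
  expect_equal(unname(f$center), c(0, 0), tolerance = 1e-9)
  expect_error(fit_cross_section(cbind(1:4, 2 * (1:4)), "circle"),
               "collinear")
  expect_error(fit_cross_section(matrix(0, 2, 2), "circle"), "at least")
})

test_that("ellipse fits recover semi-axes from exact conic samples", {
  th <- 2 * pi * (0:7) / 8
  pts <- cbind(2 * cos(th), 1 * sin(th))
  f <- fit_cross_section(pts, "ellipse")
  expect_equal(f$axes, c(2, 1), tolerance = 1e-6)
  expect_equal(unname(f$center), c(0, 0), tolerance = 1e-6)
  # rotated and shifted
  a <- pi / 5
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  pts2 <- sweep(pts %*% t(Rm), 2, c(3, -2), "+")
  f2 <- fit_cross_section(pts2, "ellipse")
  expect_equal(f2$axes, c(2, 1), tolerance = 1e-6)
  expect_equal(unname(f2$center), c(3, -2), tolerance = 1e-6)
})

test_that("polygon mode sorts boundary points in circular direction", {
  set.seed(4)
  th <- sort(runif(10, 0, 2 * pi))
  r <- 2 + 0.3 * cos(2 * th)
  pts <- cbind(r * cos(th), r * sin(th))[sample(10), ]
  f <- fit_cross_section(pts, "polygon")
  expect_true(all(diff(f$angles) > 0))
  expect_equal(nrow(f$points), 10)
})

test_that("patch construction on a cylinder returns boundary points at the radius", {
  ph <- cylinder_phantom(alpha2 = 90)
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]])
  rc <- reconstruct_centerline(ph$views[[1]]$centerlines[[1]],
                               ph$views[[2]]$centerlines[[1]], cal)
  views <- list(
    list(c2d = rc$match$c1, borders = ph$views[[1]]$borders[[1]],
         pose = cal$pose1, s_of_t = rc$s1_of_t),
    list(c2d = rc$match$c2, borders = ph$views[[2]]$borders[[1]],
         pose = cal$pose2, s_of_t = rc$s2_of_t))
  for (t in c(0.25, 0.5, 0.75)) {
    p <- build_patch(t, rc, views)
    expect_true(p$complete)
    expect_equal(nrow(p$points2d), 4)       # two per contributing view
    rad <- sqrt(rowSums(sweep(p$points2d, 2, c(0, 0))^2))
    expect_lt(max(abs(rad - 1.5)), 0.02)
  }
  # identical views carry no cross-sectional information
  views_same <- views[c(1, 1)]
  p <- build_patch(0.5, rc, views_same)
  expect_true(p$ill_conditioned)
})

test_that("a stack of identical circles assembles into an exact cylinder", {
  br <- make_tube_branch(line_pts(c(0, 0, 0), c(0, 30, 0)), 2)
  surf <- br$surface
  # exact at the circular interpolation sites, and within the periodic
  # cubic's approximation error (~1e-4 relative at w = 16) in between
  vs <- (seq_len(surf$w) - 1) / surf$w
  G <- eval_surface(surf, seq(0.1, 0.9, length.out = 7), vs)
  for (i in 1:7) {
    r <- sqrt(G[i, , 1]^2 + G[i, , 3]^2)
    expect_lt(max(abs(r - 2)), 1e-9)
  }
  set.seed(1)
  Gm <- eval_surface(surf, seq(0.1, 0.9, length.out = 7), runif(9))
  for (i in 1:7) {
    r <- sqrt(Gm[i, , 1]^2 + Gm[i, , 3]^2)
    expect_lt(max(abs(r - 2)), 1e-3 * 2)
  }
  # clamped end: u = 0 evaluates on the first patch ring
  G0 <- eval_surface(surf, 0, c(0, 0.25, 0.5))
  expect_lt(max(abs(G0[1, , 2])), 1e-9)
  expect_equal(sqrt(G0[1, 1, 1]^2 + G0[1, 1, 3]^2), 2, tolerance = 1e-9)
})

test_that("the tensor-product basis partitions unity", {
  set.seed(5)
  br <- make_tube_branch(line_pts(c(0, 0, 0), c(0, 10, 0)), 1)
  surf <- br$surface
  Bu <- coroxr:::bspline_basis(runif(20), surf$uknots, surf$k)
  Bv <- coroxr:::periodic_basis(runif(20), surf$w, surf$l)
  expect_lt(max(abs(rowSums(Bu) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(Bv) - 1)), 1e-9)
})

test_that("a torus-arc phantom is reconstructed within 1% of its tube radius", {
  # circular-arc centerline, constant radius: the surface is a torus patch
  th <- seq(0, pi / 2, length.out = 30)
  pts <- cbind(30 * cos(th), 30 * sin(th), 0)
  br <- make_tube_branch(pts, 2, q = 30)
  tm <- surface_to_mesh(br$surface, nu = 50, nv = 24)
  # analytic torus: distance from the centerline circle must equal 2
  rho <- sqrt(tm$vertices[, 1]^2 + tm$vertices[, 2]^2)
  d <- sqrt((rho - 30)^2 + tm$vertices[, 3]^2)
  expect_lt(max(abs(d - 2)), 0.02)
})

test_that("cross-section boundary points lie in the normal-binormal plane", {
  ph <- cylinder_phantom(alpha2 = 70)
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]])
  rec <- reconstruct_branch(ph$views[[1]]$centerlines[[1]],
                            ph$views[[2]]$centerlines[[1]],
                            ph$views[[1]]$borders[[1]],
                            ph$views[[2]]$borders[[1]], cal, q = 10)
  for (p in rec$patches) {
    # points2d are by construction coordinates in the N-B plane; verify the
    # frame is orthonormal and anchored on the curve
    G <- rbind(p$frame$T, p$frame$N, p$frame$B)
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-9)
  }
})
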