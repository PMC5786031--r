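test_that("gantry rotation is orthonormal with unit determinant", {
  expect_equal(rotation_matrix(0, 0), diag(3))
  for (a in seq(-180, 180, by = 5)) {
    for (b in seq(-90, 90, by = 15)) {
      M <- rotation_matrix(a, b)
      expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-12)
      expect_equal(det(M), 1, tolerance = 1e-12)
    }
  }
})

test_that("combined rotation equals the product of single-angle rotations", {
  M <- rotation_matrix(30, 20)
  expect_equal(M, rotation_matrix(0, 20) %*% rotation_matrix(30, 0),
               tolerance = 1e-12)
})

test_that("source and detector origin follow the gantry geometry", {
  so <- source_and_origin(gantry_pose(0, 0, sod = 765, sid = 1100))
  expect_equal(so$F, c(0, 0, -765))
  expect_equal(so$O, c(0, 0, 335))
  # rigid rotation preserves the source-detector separation
  for (a in c(-120, 35, 90)) {
    so <- source_and_origin(gantry_pose(a, 25, sod = 700, sid = 1050))
    expect_equal(sqrt(sum((so$F - so$O)^2)), 1050, tolerance = 1e-9)
  }
  # a pure primary rotation keeps the source at sod from the isocenter,
  # in the plane orthogonal to the rotation axis
  so <- source_and_origin(gantry_pose(90, 0, sod = 700, sid = 1100))
  expect_equal(sqrt(sum(so$F^2)), 700, tolerance = 1e-9)
  expect_equal(so$F, as.numeric(rotation_matrix(90, 0) %*% c(0, 0, -700)))
})

test_that("detector-to-world mapping honours offsets and isometry", {
  pose <- gantry_pose(0, 0)
  O <- source_and_origin(pose)$O
  expect_equal(detector_to_world(c(0, 0), pose), O)
  expect_equal(detector_to_world(c(10, 0), pose), O + c(10, 0, 0))
  pose2 <- gantry_pose(40, -15, dtheta = c(1, 2, -1), dO = c(3, -2, 1),
                       di = c(2, -4, 1))
  a <- detector_to_world(c(5, 7), pose2)
  b <- detector_to_world(c(5, 8), pose2)
  expect_equal(sqrt(sum((a - b)^2)), 1, tolerance = 1e-12)
})

test_that("forward projection inverts detector placement to 1e-9 mm", {
  set.seed(11)
  for (rep in 1:5) {
    pose <- gantry_pose(runif(1, -90, 90), runif(1, -30, 30),
                        dtheta = runif(3, -3, 3), dO = runif(3, -5, 5),
                        di = runif(3, -5, 5))
    p <- matrix(runif(40, -60, 60), 20, 2)
    W <- detector_to_world(p, pose)
    expect_lt(max(abs(forward_project(W, pose) - p)), 1e-9)
  }
  # the principal ray and the isocenter both hit the detector origin
  pose <- gantry_pose(0, 0)
  so <- source_and_origin(pose)
  mid <- (so$F + so$O) / 2
  expect_equal(forward_project(mid, pose), c(0, 0), tolerance = 1e-9)
  expect_equal(forward_project(c(0, 0, 0), pose), c(0, 0), tolerance = 1e-9)
})

test_that("triangulation returns the common-perpendicular midpoint and gap", {
  tr <- triangulate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(0, 1, 0))
  expect_equal(tr$point, c(0, 0, 0.5))
  expect_equal(tr$gap, 1)
  # symmetric in its arguments
  tr2 <- triangulate(c(0, 1, 1), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(tr2$point, tr$point)
  expect_equal(tr2$gap, tr$gap)
  # near-parallel rays are flagged with the condition measure
  tr3 <- triangulate(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1e-10, 0))
  expect_true(tr3$ill_conditioned)
  expect_lt(tr3$condition, 1e-8)
})

test_that("triangulation is rigid-motion equivariant", {
  set.seed(4)
  R <- rotation_matrix(33, 21); tvec <- c(5, -3, 7)
  o1 <- runif(3); d1 <- runif(3); o2 <- runif(3, 1, 2); d2 <- runif(3, -1, 0)
  a <- triangulate(o1, d1, o2, d2)
  b <- triangulate(as.numeric(R %*% o1) + tvec, as.numeric(R %*% d1),
                   as.numeric(R %*% o2) + tvec, as.numeric(R %*% d2))
  expect_equal(b$point, as.numeric(R %*% a$point) + tvec, tolerance = 1e-9)
  expect_equal(b$gap, a$gap, tolerance = 1e-9)
})

test_that("two-view triangulation recovers world points exactly", {
  set.seed(21)
  pose1 <- gantry_pose(0, 0)
  pose2 <- gantry_pose(55, 20, dtheta = c(1, -2, 1), dO = c(2, 3, -1),
                       di = c(-2, 1, 3))
  P <- matrix(runif(300, -40, 40), 100, 3)
  q1 <- forward_project(P, pose1)
  q2 <- forward_project(P, pose2)
  tri <- coroxr:::.triangulate_views(q1, q2, pose1, pose2)
  expect_lt(max(abs(tri$points - P)), 1e-6)
  expect_lt(max(tri$gap), 1e-6)
})
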