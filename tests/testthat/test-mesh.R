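test_that("patch node and quad counts follow the O-grid pattern", {
  for (v in c(4, 8, 16)) {
    th <- 2 * pi * (seq_len(v) - 1) / v
    p <- make_patch(c(0, 0, 0), cbind(cos(th), sin(th), 0), v)
    expect_equal(nrow(p$nodes), 2 * v + 1)
    expect_equal(nrow(p$quads), 3 * v / 2)
  }
  expect_error(make_patch(c(0, 0, 0), matrix(0, 6, 3), 6), "multiple of 4")
})

test_that("inner-ring nodes sit at 45% of the outer radius", {
  th <- 2 * pi * (0:7) / 8
  p <- make_patch(c(0, 0, 0), cbind(cos(th), sin(th), 0), 8)
  inner_r <- sqrt(rowSums(p$nodes[2:9, ]^2))
  expect_equal(inner_r, rep(0.45, 8), tolerance = 1e-12)
})

test_that("patch quads of a circular ring are consistently oriented", {
  th <- 2 * pi * (0:7) / 8
  p <- make_patch(c(0, 0, 0), cbind(cos(th), sin(th), 0), 8)
  shoelace <- function(q) {
    x <- p$nodes[q, 1]; y <- p$nodes[q, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  areas <- apply(p$quads, 1, shoelace)
  expect_true(all(areas > 0))
})

test_that("sweeping patches produces the expected hexahedra", {
  th <- 2 * pi * (0:7) / 8
  patches <- lapply(0:10, function(i)
    make_patch(c(0, 0, i), cbind(1.5 * cos(th), 1.5 * sin(th), i), 8))
  hm <- sweep_hexes(patches)
  expect_equal(nrow(hm$hexes), 120)          # 10 layers x 12 quads
  inc <- mesh_face_incidence(hm)
  expect_true(all(names(inc) %in% c("1", "2")))
})

test_that("scaled Jacobian reproduces closed-form element values", {
  cube <- structure(list(nodes = rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                                       c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),
                         hexes = matrix(1:8, 1), v = 4), class = "hex_mesh")
  expect_equal(mesh_quality(cube)$min, 1)
  shear <- cube; shear$nodes[5:8, 1] <- shear$nodes[5:8, 1] + 1
  expect_equal(mesh_quality(shear)$min, sqrt(2) / 2, tolerance = 1e-12)
  inv <- cube; inv$nodes[c(1, 2), ] <- inv$nodes[c(2, 1), ]
  expect_lt(mesh_quality(inv)$min, 0)
})

test_that("an ideal cylinder mesh scores the pattern's intrinsic quality", {
  # the 45% regular inner ring makes the core-quad corners subtend 135
  # degrees, so the corner-based metric is sin(135 deg) there and the ring
  # elements score sin(67.5 deg)^2-based 0.9239; the centroid metric is
  # insensitive to the corner angle
  th <- 2 * pi * (0:7) / 8
  patches <- lapply(0:10, function(i)
    make_patch(c(0, 0, i), cbind(1.5 * cos(th), 1.5 * sin(th), i), 8))
  hm <- sweep_hexes(patches)
  q <- mesh_quality(hm)
  vals <- sort(unique(round(q$jacobian, 4)))
  expect_equal(vals, c(0.7071, 0.9239))
  expect_gt(mesh_quality(hm, at = "centroid")$min, 0.9)
})

test_that("frame smoothing re-seeds children and is idempotent", {
  tr <- make_y_tree()
  tr1 <- smooth_trihedrons(tr)
  tr2 <- smooth_trihedrons(tr1)
  for (i in 1:3) {
    expect_equal(tr1$branches[[i]]$centerline$frames$N,
                 tr2$branches[[i]]$centerline$frames$N, tolerance = 1e-12)
  }
  # child frames continue the parent end-trihedron: the child's first
  # normal is close to the parent's last (rotated by the 30-degree bend)
  pf <- tr1$branches[[1]]$centerline$frames
  cf <- tr1$branches[[2]]$centerline$frames
  expect_gt(sum(pf$N[nrow(pf$N), ] * cf$N[1, ]), cos(35 * pi / 180))
})

test_that("frames rotate continuously through a 90-degree planar bend", {
  th <- seq(0, pi / 2, length.out = 40)
  pts <- cbind(20 * cos(th), 20 * sin(th), 0)
  br <- make_tube_branch(pts, 1.5)
  fr <- br$centerline$frames
  dots <- rowSums(fr$N[-1, ] * fr$N[-nrow(fr$N), ])
  expect_true(all(dots > 0))
  expect_true(all(acos(pmin(1, dots)) < 15 * pi / 180))
})

test_that("a Y junction merges into a conforming watertight hex mesh", {
  tr <- make_y_tree()
  hm <- trim_and_merge(tr, v = 8, n_long = 30)
  inc <- mesh_face_incidence(hm)
  expect_true(all(names(inc) %in% c("1", "2")))
  q <- mesh_quality(hm)
  expect_true(all(q$jacobian > 0))           # no inverted elements
  # coarser circular subdivision still conforms, with fewer elements
  hm4 <- trim_and_merge(tr, v = 4, n_long = 30)
  inc4 <- mesh_face_incidence(hm4)
  expect_true(all(names(inc4) %in% c("1", "2")))
  expect_lt(nrow(hm4$hexes), nrow(hm$hexes))
})

test_that("a single branch needs no trimming and matches the plain sweep", {
  br <- make_tube_branch(line_pts(c(0, 0, 0), c(0, 25, 0)), 1.5)
  tr <- coronary_tree(list(br), NA)
  hm1 <- trim_and_merge(tr, v = 8, n_long = 12)
  hm2 <- mesh_branch(br$surface, n_long = 12, v = 8)
  expect_equal(nrow(hm1$hexes), nrow(hm2$hexes))
  expect_equal(nrow(hm1$nodes), nrow(hm2$nodes))
})

test_that("doubling the circular subdivision keeps the surface geometry", {
  br <- make_tube_branch(line_pts(c(0, 0, 0), c(0, 25, 0)), 1.5)
  for (v in c(8, 16)) {
    hm <- mesh_branch(br$surface, n_long = 10, v = v)
    outer_nodes <- hm$nodes[sqrt(hm$nodes[, 1]^2 + hm$nodes[, 3]^2) > 1, ]
    r <- sqrt(outer_nodes[, 1]^2 + outer_nodes[, 3]^2)
    expect_lt(max(abs(r - 1.5)), 1e-6)
  }
})
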