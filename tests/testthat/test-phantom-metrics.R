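test_that("projected silhouette borders show the analytic magnification", {
  # straight tube along y through the isocenter, AP view: tangency from the
  # focal point at distance D from the axis gives a projected half-width of
  # d_sid * tan(asin(r / D))
  pose1 <- gantry_pose(0, 0, sod = 765, sid = 1100)
  br <- branch_line(c(0, -20, 0), c(0, 1, 0), 40, 1.5)
  ph <- generate_phantom(phantom_spec(list(br), NA, list(pose1), seed = 1))
  b <- ph$views[[1]]$borders[[1]]
  sep <- abs(b[[1]][, 1] - b[[2]][, 1])
  expected <- 2 * 1100 * tan(asin(1.5 / 765))
  expect_lt(max(abs(sep - expected)), 1e-6)
})

test_that("phantom generation is deterministic given the seed", {
  s <- phantom_spec(list(branch_line(c(0, -10, 0), c(0.2, 1, 0), 30, 1.2)),
                    NA, list(gantry_pose(0, 0), gantry_pose(45, 10)),
                    noise_px = 0.7,
                    frames = list(n = c(10, 12), period = 8, phase_shift = 2,
                                  amplitude = 2), seed = 17)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$views[[1]]$centerlines, b$views[[1]]$centerlines)
  expect_identical(a$frame_sequences, b$frame_sequences)
})

test_that("a 50% stenosis halves the projected border separation", {
  pose1 <- gantry_pose(0, 0)
  mk <- function(sten) {
    br <- branch_line(c(0, -20, 0), c(0, 1, 0), 40, 1.5, stenosis = sten)
    generate_phantom(phantom_spec(list(br), NA, list(pose1), seed = 1))
  }
  ph0 <- mk(NULL)
  ph1 <- mk(list(depth = 0.5, at = 0.5, width = 0.08))
  sep0 <- abs(ph0$views[[1]]$borders[[1]][[1]][, 1] -
              ph0$views[[1]]$borders[[1]][[2]][, 1])
  sep1 <- abs(ph1$views[[1]]$borders[[1]][[1]][, 1] -
              ph1$views[[1]]$borders[[1]][[2]][, 1])
  expect_equal(min(sep1) / stats::median(sep0), 0.5, tolerance = 0.02)
})

test_that("signed deviation separates identical, inflated and deflated surfaces", {
  s10 <- make_sphere_mesh(10)
  s9 <- make_sphere_mesh(9)
  d0 <- signed_deviation(s10, s10)
  expect_lt(max(abs(d0$deviation)), 1e-9)
  d_out <- signed_deviation(s10, s9)        # test outside reference
  expect_equal(mean(d_out$deviation), 1, tolerance = 1e-2)
  expect_true(all(d_out$deviation > 0.9))
  d_in <- signed_deviation(s9, s10)         # swapped: everything inside
  expect_equal(mean(d_in$deviation), -1, tolerance = 1e-2)
  expect_true(all(d_in$deviation < -0.9))
})

test_that("Hausdorff distance is symmetric, zero on identity, metric-like", {
  s10 <- make_sphere_mesh(10)
  s9 <- make_sphere_mesh(9)
  expect_equal(hausdorff_distance(s10, s10)$max, 0)
  expect_equal(hausdorff_distance(s10, s9)$max, 1, tolerance = 1e-2)
  a <- make_sphere_mesh(8)
  b <- make_sphere_mesh(9.5, center = c(0.4, 0, 0))
  cc <- make_sphere_mesh(11, center = c(-0.3, 0.2, 0))
  dab <- hausdorff_distance(a, b)$max
  dbc <- hausdorff_distance(b, cc)$max
  dac <- hausdorff_distance(a, cc)$max
  expect_lte(dac, dab + dbc + 1e-9)
})

test_that("length agreement statistics match a direct recomputation", {
  la <- length_agreement(c(10, 20, 30), c(10, 20, 30))
  expect_equal(la$r_squared, 1)
  expect_equal(la$mean_diff, 0)
  la2 <- length_agreement(c(10, 20, 30) + 2.5, c(10, 20, 30))
  expect_equal(la2$r_squared, 1)
  expect_equal(la2$mean_diff, 2.5)
  set.seed(31)
  truth <- runif(20, 20, 80)
  recon <- truth + rnorm(20, 0.2, 0.8)
  la3 <- length_agreement(recon, truth)
  d <- recon - truth
  expect_equal(la3$r_squared, cor(recon, truth)^2)
  expect_equal(la3$mean_diff, mean(d))
  expect_equal(la3$mean_abs_diff, mean(abs(d)))
  expect_equal(la3$sd_diff, sd(d))
  expect_equal(la3$bland_altman[, "mean"], (recon + truth) / 2)
  expect_error(length_agreement(1:2, 1:2))
})

test_that("rendered phantom views show a dark vessel on bright background", {
  ph <- cylinder_phantom(n_samples = 120)
  img <- render_view(ph, 1, dim = c(150, 150))
  expect_equal(dim(img), c(150, 150))
  expect_lt(min(img), 0.3)
  expect_equal(max(img), 1)
})

test_that("rigid ICP recovers a small misalignment of a tube mesh", {
  br <- make_tube_branch(line_pts(c(0, 0, 0), c(5, 25, 3)), 2)
  ref <- surface_to_mesh(br$surface, 30, 18)
  R <- rotation_matrix(2.5, -1.5)
  moved <- ref
  moved$vertices <- sweep(ref$vertices %*% t(R), 2, c(0.8, -0.5, 0.4), "+")
  back <- align_icp(moved, ref)
  expect_lt(attr(back, "rmse"), 0.05)
  d <- signed_deviation(back, ref)
  expect_lt(d$summary$mean_abs, 0.05)
})
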