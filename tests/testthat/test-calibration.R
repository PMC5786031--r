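test_that("reprojection MSE is zero at the generating geometry", {
  set.seed(3)
  P <- matrix(runif(18, -30, 30), 6, 3)
  pose1 <- ap_pose()
  true2 <- gantry_pose(30, 20, dtheta = c(1, -2, 0.5), dO = c(2, -1, 3),
                       di = c(-1, 2, 1))
  q1 <- forward_project(P, pose1)
  q2 <- forward_project(P, true2)
  base <- list(pose1, gantry_pose(30, 20))
  expect_lt(reprojection_mse(coroxr:::.params_of_pose(true2), q1, q2, base),
            1e-12)
  # a 5-degree angle error strictly increases the objective
  pert <- coroxr:::.params_of_pose(true2); pert[1] <- pert[1] + 5
  expect_gt(reprojection_mse(pert, q1, q2, base), 0.1)
  # defined even for a single point pair
  v <- reprojection_mse(coroxr:::.params_of_pose(true2), q1[1, , drop = FALSE],
                        q2[1, , drop = FALSE], base)
  expect_true(is.finite(v) && v >= 0)
})

test_that("calibration at an unperturbed geometry stays at the header values", {
  set.seed(5)
  P <- matrix(runif(18, -35, 35), 6, 3)
  pose1 <- ap_pose()
  true2 <- gantry_pose(30, 20)              # no misalignment at all
  q1 <- forward_project(P, pose1)
  q2 <- forward_project(P, true2)
  cal <- calibrate(q1, q2, list(pose1, gantry_pose(30, 20)), fast_ga(seed = 2))
  expect_lt(cal$mse, 1e-4)
  expect_lt(abs(cal$params[1] - 30), 0.2)
  expect_lt(abs(cal$params[2] - 20), 0.2)
  expect_true(all(diff(cal$history) <= 1e-12))
})

test_that("calibration needs two points and a nonempty search box", {
  q <- matrix(0, 1, 2)
  expect_error(calibrate(q, q, list(ap_pose(), gantry_pose(30, 0))),
               "at least 2")
})

test_that("the best-fitness trajectory is non-increasing across generations", {
  set.seed(6)
  P <- matrix(runif(18, -30, 30), 6, 3)
  pose1 <- ap_pose()
  true2 <- gantry_pose(25, -10, dtheta = c(2, 1, -1), dO = c(-2, 3, 1),
                       di = c(1, -2, 2))
  q1 <- forward_project(P, pose1); q2 <- forward_project(P, true2)
  cal <- calibrate(q1, q2, list(pose1, gantry_pose(25, -10)), fast_ga(seed = 4))
  expect_true(all(diff(cal$history) <= 1e-12))
  expect_lte(cal$mse,
             reprojection_mse(coroxr:::.params_of_pose(gantry_pose(25, -10)),
                              q1, q2, list(pose1, gantry_pose(25, -10))))
})

test_that("the calibration error grows monotonically with 2D noise", {
  set.seed(7)
  P <- matrix(runif(18, -30, 30), 6, 3)
  pose1 <- ap_pose()
  true2 <- gantry_pose(35, 15, dO = c(2, -1, 1), di = c(1, 1, -2))
  q1 <- forward_project(P, pose1); q2 <- forward_project(P, true2)
  base <- list(pose1, gantry_pose(35, 15))
  mse_at <- function(noise_mm) {
    set.seed(99)
    q1n <- q1 + matrix(rnorm(length(q1), 0, noise_mm), nrow(q1), 2)
    q2n <- q2 + matrix(rnorm(length(q2), 0, noise_mm), nrow(q2), 2)
    calibrate(q1n, q2n, base, fast_ga(seed = 3))$mse
  }
  m1 <- mse_at(0.2)       # one pixel at 0.2 mm spacing
  m2 <- mse_at(0.4)
  expect_gt(m2, m1)
})

test_that("coef and summary expose the eleven device parameters", {
  cal <- known_calibration(ap_pose(), gantry_pose(40, 5), mse = 0.5)
  cf <- coef(cal)
  expect_length(cf, 11)
  expect_equal(unname(cf[1:2]), c(40, 5))
  expect_output(print(cal), "MSE")
})
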