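test_that("the centerline skip penalty follows the calibration error", {
  ph <- cylinder_phantom()
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]], mse = 2)
  m <- match_centerlines(ph$views[[1]]$centerlines[[1]],
                         ph$views[[2]]$centerlines[[1]], cal, resample = 40)
  expect_equal(m$xi, 2 * sqrt(2))
})

test_that("projections of one branch match monotonically and triangulate", {
  ph <- cylinder_phantom()
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]])
  m <- match_centerlines(ph$views[[1]]$centerlines[[1]],
                         ph$views[[2]]$centerlines[[1]], cal)
  expect_gt(nrow(m$pairs), 60)
  expect_true(all(diff(m$pairs[, 1]) > 0))
  expect_true(all(diff(m$pairs[, 2]) > 0))
  # triangulated points lie on the true axis: 0.05 mm RMS (individual
  # points carry the arc-sampling quantization of the 100-point polylines)
  d0 <- unit_vec(c(0.15, 1, 0.1))
  rel <- sweep(m$points3d, 2, c(-5, -20, 2))
  perp <- rel - outer(as.numeric(rel %*% d0), d0)
  expect_lt(sqrt(mean(rowSums(perp^2))), 0.05)
  expect_lt(max(sqrt(rowSums(perp^2))), 0.15)
})

test_that("overextended distal segmentation is skipped, not force-matched", {
  ph <- cylinder_phantom()
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]])
  c1 <- ph$views[[1]]$centerlines[[1]]
  c2 <- ph$views[[2]]$centerlines[[1]]
  # extend the secondary projection ~20% past the true distal end
  dirend <- c2[nrow(c2), ] - c2[nrow(c2) - 1, ]
  dirend <- dirend / sqrt(sum(dirend^2))
  ext <- sweep(outer(seq(0.4, 8, by = 0.4), dirend), 2, c2[nrow(c2), ], "+")
  m0 <- match_centerlines(c1, c2, cal)
  mx <- match_centerlines(c1, rbind(c2, ext), cal)
  # the true extent is matched; the appended points are not
  expect_lt(max(mx$s2), 0.9)
  expect_gt(max(mx$s2), 0.7)
  expect_true(all(diff(mx$pairs[, 2]) > 0))
  # skipping grows with the overextension, not with the true extent
  expect_lte(nrow(mx$pairs), nrow(m0$pairs) + 5)
})

test_that("reconstruction recovers branch length and shape on a phantom", {
  ph <- cylinder_phantom()
  cal <- known_calibration(ph$spec$poses[[1]], ph$spec$poses[[2]])
  rc <- reconstruct_centerline(ph$views[[1]]$centerlines[[1]],
                               ph$views[[2]]$centerlines[[1]], cal)
  truth_len <- ph$branches[[1]]$length
  recon_len <- bspline_length(rc$curve)
  expect_lt(abs(recon_len - truth_len) / truth_len, 0.01)
  d0 <- unit_vec(c(0.15, 1, 0.1))
  rel <- sweep(rc$samples, 2, c(-5, -20, 2))
  perp <- rel - outer(as.numeric(rel %*% d0), d0)
  expect_lt(sqrt(mean(rowSums(perp^2))), 0.1)
  # the view-parameter maps are monotone
  tt <- seq(0, 1, length.out = 25)
  expect_true(all(diff(rc$s1_of_t(tt)) >= 0))
  expect_true(all(diff(rc$s2_of_t(tt)) >= 0))
})

test_that("matching requires a calibration object", {
  expect_error(match_centerlines(matrix(0, 5, 2), matrix(0, 5, 2),
                                 list(mse = 1)), "calibration")
})
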