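# ---------------------------------------------------------------------------
# 3D centerline reconstruction: elastic partial matching of the two 2D
# projections, triangulation of the matched pairs, B-spline fit and frames.
# ---------------------------------------------------------------------------

# dissimilarity matrix for centerline-point matching: for every (r, t) pair
# the candidate 3D point is triangulated and ray-traced back into both
# views; delta is the sum of the two squared 2D residuals (mm^2).
.centerline_delta <- function(c1, c2, pose1, pose2) {
  f1 <- .pose_frame(pose1); f2 <- .pose_frame(pose2)
  P1 <- sweep(c1 %*% rbind(f1$eu, f1$ev), 2, f1$X0, "+")
  P2 <- sweep(c2 %*% rbind(f2$eu, f2$ev), 2, f2$X0, "+")
  D1 <- sweep(P1, 2, f1$F)                      # g x 3
  D2 <- sweep(P2, 2, f2$F)                      # h x 3
  a <- rowSums(D1 * D1); cc <- rowSums(D2 * D2)
  b <- D1 %*% t(D2)                             # g x h
  w <- f2$F - f1$F
  e <- as.numeric(D1 %*% w); f <- as.numeric(D2 %*% w)
  det <- outer(a, cc) - b^2
  s <- (sweep(b, 2, f, "*") * -1 + outer(e, cc)) / det
  tt <- (b * e - outer(a, f)) / det
  X <- lapply(1:3, function(j) {
    0.5 * (f1$F[j] + s * D1[, j] + f2$F[j] + sweep(tt, 2, D2[, j], "*"))
  })
  # reproject into both views
  reproj <- function(fr) {
    dx <- X[[1]] - fr$F[1]; dy <- X[[2]] - fr$F[2]; dz <- X[[3]] - fr$F[3]
    den <- dx * fr$en[1] + dy * fr$en[2] + dz * fr$en[3]
    sc <- as.numeric((fr$X0 - fr$F) %*% fr$en) / den
    ix <- fr$F[1] + sc * dx - fr$X0[1]
    iy <- fr$F[2] + sc * dy - fr$X0[2]
    iz <- fr$F[3] + sc * dz - fr$X0[3]
    list(u = ix * fr$eu[1] + iy * fr$eu[2] + iz * fr$eu[3],
         v = ix * fr$ev[1] + iy * fr$ev[2] + iz * fr$ev[3])
  }
  r1 <- reproj(f1); r2 <- reproj(f2)
  d1 <- (r1$u - c1[, 1])^2 + (r1$v - c1[, 2])^2    # varies along rows
  d2 <- (sweep(r2$u, 2, c2[, 1]))^2 + (sweep(r2$v, 2, c2[, 2]))^2
  delta <- d1 + d2
  list(delta = delta, X = X)
}

#' Match two projected centerlines and triangulate
#'
#' Establishes a strictly monotone one-to-one point correspondence between
#' the two 2D projections of a vessel centerline by optimal subsequence
#' bijection, where the dissimilarity of pairing point r (view 1) with point
#' t (view 2) is the two-view reprojection error of their triangulated 3D
#' point, and the skip penalty is \code{sqrt(2)} times the calibration error.
#' Points of either projection with no counterpart (over-segmented ends,
#' spurious extensions) are skipped rather than force-matched.
#'
#' @param c1,c2 matrices of ordered 2D centerline points in detector mm
#'   (primary / secondary view), at least 2 rows each.
#' @param calib an \code{xra_calibration}; its \code{mse} sets the skip
#'   penalty.  When the calibration error is essentially zero (exact
#'   synthetic geometry) the generic penalty derived from the
#'   dissimilarity matrix itself (\code{\link{skip_penalty}}) is used
#'   instead, since a zero penalty would make every skip free.
#' @param resample number of arc-length samples per centerline before
#'   matching (default 100); use NULL to match the raw points.
#' @return list with \code{pairs} (matched index pairs into the resampled
#'   polylines), \code{points3d} (matched triangulated 3D points),
#'   \code{s1}, \code{s2} (arc parameters of the matched points on each
#'   projection), \code{cost} and \code{xi}.
#' @export
match_centerlines <- function(c1, c2, calib, resample = 100) {
  if (!inherits(calib, "xra_calibration"))
    stop("calibration is required for centerline matching")
  c1 <- as.matrix(c1); c2 <- as.matrix(c2)
  stopifnot(nrow(c1) >= 2, nrow(c2) >= 2)
  if (!is.null(resample)) {
    c1 <- resample_polyline(c1, resample)
    c2 <- resample_polyline(c2, resample)
  }
  dd <- .centerline_delta(c1, c2, calib$pose1, calib$pose2)
  # the skip penalty follows the calibration error; with (near-)exact
  # synthetic geometry that error vanishes and every skip would be free, so
  # the generic dissimilarity-derived penalty takes over
  xi <- sqrt(2) * calib$mse
  if (calib$mse < 1e-9) xi <- skip_penalty(dd$delta)
  path <- osb_match(dd$delta, xi)
  pr <- path$pairs
  pts <- cbind(dd$X[[1]][pr], dd$X[[2]][pr], dd$X[[3]][pr])
  s1 <- polyline_params(c1); s2 <- polyline_params(c2)
  list(pairs = pr, points3d = pts,
       s1 = s1[pr[, 1]], s2 = s2[pr[, 2]],
       cost = path$cost, xi = xi, c1 = c1, c2 = c2)
}

#' Reconstruct a 3D branch centerline from its two projections
#'
#' Runs \code{\link{match_centerlines}}, fits a clamped B-spline through the
#' triangulated points (chord-length knots) and attaches moving frames.
#'
#' @inheritParams match_centerlines
#' @param k spline order (default 4, cubic).
#' @param n_ctrl number of control points passed to
#'   \code{\link{fit_bspline}}.
#' @param n_frames number of frame samples along the curve.
#' @return object of class \code{branch_centerline}: the fitted
#'   \code{curve}, triangulated \code{samples}, \code{frames}
#'   (Frenet/rotation-minimizing triads), the \code{match} result, and
#'   monotone maps \code{s1_of_t}, \code{s2_of_t} from curve parameter to
#'   the arc parameter of each 2D projection.
#' @export
reconstruct_centerline <- function(c1, c2, calib, resample = 100, k = 4,
                                   n_ctrl = NULL, n_frames = 100) {
  m <- match_centerlines(c1, c2, calib, resample)
  if (nrow(m$points3d) < k)
    stop("too few matched points to fit the centerline spline")
  curve <- fit_bspline(m$points3d, k = k, n_ctrl = n_ctrl)
  ts <- seq(0, 1, length.out = n_frames)
  frames <- frenet_frames(curve, ts, method = "rmf")
  tb <- curve$tbar
  structure(list(curve = curve, samples = m$points3d, frames = frames,
                 match = m,
                 s1_of_t = function(t) approx(tb, m$s1, xout = t, rule = 2)$y,
                 s2_of_t = function(t) approx(tb, m$s2, xout = t, rule = 2)$y),
            class = "branch_centerline")
}

#' @export
print.branch_centerline <- function(x, ...) {
  cat(sprintf("Reconstructed branch centerline: %d matched points, length %.2f mm\n",
              nrow(x$samples), bspline_length(x$curve)))
  invisible(x)
}
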