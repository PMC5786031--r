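#' @useDynLib coroxr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor dist fft optim rnorm runif sd spline var
#' @importFrom utils head read.csv tail write.csv
NULL

.deg <- function(x) x * pi / 180

#' C-arm gantry pose
#'
#' Describes the projective geometry of one X-ray angiography (XRA) view: the
#' positioner angles, source/detector distances, imager pixel spacing, and the
#' misalignment terms of the non-ideal gantry (detector rotations
#' \code{dtheta}, detector translation \code{dO} and isocenter shift
#' \code{di}).  The global frame has its origin at the primary view's
#' isocenter; all lengths are millimetres and all angles degrees (LAO/CRA
#' positive, as stored in DICOM headers).
#'
#' @param alpha primary positioner angle, degrees, in [-180, 180].
#' @param beta secondary positioner angle, degrees, in [-90, 90].
#' @param sod source-to-isocenter distance (mm), 0 < sod < sid.
#' @param sid source-to-detector distance (mm).
#' @param kappa imager pixel spacing, mm/pixel, length-2 (u, v).
#' @param dtheta detector misalignment rotations (degrees, length 3).
#' @param dO detector translation offsets (mm, length 3).
#' @param di isocenter shift relative to the primary view (mm, length 3).
#' @return An object of class \code{gantry_pose}.
#' @export
gantry_pose <- function(alpha = 0, beta = 0, sod = 765, sid = 1100,
                        kappa = c(0.2, 0.2),
                        dtheta = c(0, 0, 0), dO = c(0, 0, 0), di = c(0, 0, 0)) {
  stopifnot(sid > sod, sod > 0, all(kappa > 0),
            alpha >= -180, alpha <= 180, beta >= -90, beta <= 90,
            length(dtheta) == 3, length(dO) == 3, length(di) == 3)
  structure(list(alpha = alpha, beta = beta, sod = sod, sid = sid,
                 kappa = as.numeric(kappa), dtheta = as.numeric(dtheta),
                 dO = as.numeric(dO), di = as.numeric(di)),
            class = "gantry_pose")
}

#' @export
print.gantry_pose <- function(x, ...) {
  cat(sprintf("Gantry pose: alpha = %.2f deg, beta = %.2f deg, SOD = %.0f mm, SID = %.0f mm\n",
              x$alpha, x$beta, x$sod, x$sid))
  if (any(c(x$dtheta, x$dO, x$di) != 0))
    cat(sprintf("  misalignment: dtheta = (%s) deg, dO = (%s) mm, di = (%s) mm\n",
                paste(sprintf("%.2f", x$dtheta), collapse = ", "),
                paste(sprintf("%.2f", x$dO), collapse = ", "),
                paste(sprintf("%.2f", x$di), collapse = ", ")))
  invisible(x)
}

#' Gantry rotation matrix
#'
#' The rotation taking the neutral (anterior-posterior) C-arm frame to the
#' frame positioned at primary angle \code{alpha} and secondary angle
#' \code{beta}.  Equals the composition of a rotation by \code{alpha} about
#' the patient's longitudinal axis followed by one of \code{beta} about the
#' transverse axis; orthonormal with determinant +1 for all angle pairs.
#'
#' @param alpha,beta positioner angles in degrees.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(alpha, beta) {
  a <- .deg(alpha); b <- .deg(beta)
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  matrix(c(cb,  sa * sb, ca * sb,
           0,   ca,      -sa,
           -sb, sa * cb, ca * cb),
         nrow = 3, byrow = TRUE)
}

.rot_axis <- function(angle_deg, axis) {
  t <- .deg(angle_deg); c <- cos(t); s <- sin(t)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
         y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
         z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
}

# detector misalignment rotation R_dtheta = Rx * Ry * Rz
.r_dtheta <- function(dtheta) {
  .rot_axis(dtheta[1], "x") %*% .rot_axis(dtheta[2], "y") %*% .rot_axis(dtheta[3], "z")
}

# cached per-pose frame: M, R_dtheta, focal point F, detector origin O,
# plane origin X0 (includes dO) and the detector in-plane/normal axes.
.pose_frame <- function(pose) {
  M <- rotation_matrix(pose$alpha, pose$beta)
  R <- .r_dtheta(pose$dtheta)
  RM <- R %*% M
  F <- as.numeric(M %*% c(0, 0, -pose$sod)) + pose$di
  O <- as.numeric(M %*% c(0, 0, pose$sid - pose$sod)) + pose$di
  X0 <- O + as.numeric(RM %*% pose$dO)
  list(M = M, R = R, RM = RM, F = F, O = O, X0 = X0,
       eu = RM[, 1], ev = RM[, 2], en = RM[, 3])
}

#' Focal point and detector origin of a pose
#'
#' @param pose a \code{\link{gantry_pose}}.
#' @return list with \code{F} (X-ray source) and \code{O} (origin of the
#'   projection plane), both 3-vectors in mm, including the pose's isocenter
#'   shift.
#' @export
source_and_origin <- function(pose) {
  fr <- .pose_frame(pose)
  list(F = fr$F, O = fr$O)
}

#' Map detector-plane points to world coordinates
#'
#' Places 2D detector points (mm, origin at the image center) in the global
#' 3D frame, applying the pose's detector misalignment rotation, detector
#' translation and isocenter shift.
#'
#' @param p numeric length-2 vector or n x 2 matrix of detector coordinates
#'   (mm).
#' @param pose a \code{\link{gantry_pose}}.
#' @return n x 3 matrix (or 3-vector for a single point) of world points, mm.
#' @export
detector_to_world <- function(p, pose) {
  fr <- .pose_frame(pose)
  one <- is.null(dim(p))
  p <- matrix(p, ncol = 2)
  W <- sweep(p %*% rbind(fr$eu, fr$ev), 2, fr$X0, "+")
  if (one) as.numeric(W) else W
}

#' Forward (ray-tracing) projection onto the detector
#'
#' Projects world points through the pose's focal point onto the (possibly
#' misaligned) detector plane and returns in-plane detector coordinates in
#' mm.  This inverts \code{\link{detector_to_world}}: the round trip is the
#' identity to machine precision.
#'
#' @param P numeric length-3 vector or n x 3 matrix of world points (mm).
#' @param pose a \code{\link{gantry_pose}}.
#' @return n x 2 matrix (or length-2 vector) of detector coordinates, mm.
#' @export
forward_project <- function(P, pose) {
  fr <- .pose_frame(pose)
  one <- is.null(dim(P))
  P <- matrix(P, ncol = 3)
  D <- sweep(P, 2, fr$F)                    # ray directions from F
  denom <- as.numeric(D %*% fr$en)
  if (any(abs(denom) < 1e-12))
    stop("degenerate projection: ray parallel to the detector plane")
  s <- as.numeric((fr$X0 - fr$F) %*% fr$en) / denom
  X <- sweep(D * s, 2, fr$F, "+")           # intersection with the plane
  rel <- sweep(X, 2, fr$X0)
  out <- cbind(as.numeric(rel %*% fr$eu), as.numeric(rel %*% fr$ev))
  if (one) as.numeric(out) else out
}

#' Pixel index / detector millimetre conversion
#'
#' Detector coordinates are mm with origin at the image center,
#' \code{u = (col - W/2) * kappa_u}, \code{v = (row - H/2) * kappa_v}
#' (u rightward, v downward in image space); pixel indices are 0-based.
#'
#' @param px n x 2 matrix of (col, row) pixel indices.
#' @param pose a \code{\link{gantry_pose}}.
#' @param dim image dimensions c(width, height) in pixels.
#' @return n x 2 matrix of detector mm coordinates.
#' @export
pixels_to_mm <- function(px, pose, dim) {
  px <- matrix(px, ncol = 2)
  cbind((px[, 1] - dim[1] / 2) * pose$kappa[1],
        (px[, 2] - dim[2] / 2) * pose$kappa[2])
}

#' Triangulate two rays
#'
#' Returns the midpoint of the common perpendicular segment between two
#' X-rays (the reconstructed 3D point) and the segment length (the
#' triangulation gap).  The condition measure is the sine of the angle
#' between the rays; near-parallel rays are flagged ill-conditioned.
#'
#' @param o1,d1 origin and direction of the first ray (3-vectors).
#' @param o2,d2 origin and direction of the second ray.
#' @param tol condition threshold below which the result is flagged.
#' @return list with \code{point} (3-vector), \code{gap} (mm),
#'   \code{condition} (sine of the inter-ray angle) and
#'   \code{ill_conditioned} (logical).
#' @export
triangulate <- function(o1, d1, o2, d2, tol = 1e-8) {
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  stopifnot(n1 > 0, n2 > 0)
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  w <- o2 - o1
  e <- sum(d1 * w); f <- sum(d2 * w)
  det <- a * c - b * b
  cond <- sqrt(max(det, 0)) / (n1 * n2)     # sin of the angle between rays
  if (det <= tol^2 * (n1 * n2)^2) {
    return(list(point = rep(NA_real_, 3), gap = NA_real_,
                condition = cond, ill_conditioned = TRUE))
  }
  s <- (c * e - b * f) / det
  t <- (b * e - a * f) / det
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  list(point = (p1 + p2) / 2, gap = sqrt(sum((p1 - p2)^2)),
       condition = cond, ill_conditioned = cond < tol)
}

# Vectorised two-view triangulation of detector point sets.
# q1, q2: n x 2 detector mm coordinates in view 1 / view 2.
# Returns list(points = n x 3, gap = n).
.triangulate_views <- function(q1, q2, pose1, pose2) {
  f1 <- .pose_frame(pose1); f2 <- .pose_frame(pose2)
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  P1 <- sweep(q1 %*% rbind(f1$eu, f1$ev), 2, f1$X0, "+")
  P2 <- sweep(q2 %*% rbind(f2$eu, f2$ev), 2, f2$X0, "+")
  D1 <- sweep(P1, 2, f1$F)
  D2 <- sweep(P2, 2, f2$F)
  a <- rowSums(D1 * D1); b <- rowSums(D1 * D2); c <- rowSums(D2 * D2)
  w <- matrix(f2$F - f1$F, nrow(D1), 3, byrow = TRUE)
  e <- rowSums(D1 * w); f <- rowSums(D2 * w)
  det <- a * c - b * b
  s <- (c * e - b * f) / det
  t <- (b * e - a * f) / det
  p1 <- sweep(D1 * s, 2, f1$F, "+")
  p2 <- sweep(D2 * t, 2, f2$F, "+")
  list(points = (p1 + p2) / 2, gap = sqrt(rowSums((p1 - p2)^2)))
}
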