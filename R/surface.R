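# ---------------------------------------------------------------------------
# Lumen cross-section construction and NURBS tensor-product surface assembly.
# ---------------------------------------------------------------------------

# closest points of two lines (o1 + s d1, o2 + t d2); returns both feet
.closest_points <- function(o1, d1, o2, d2) {
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  w <- o2 - o1
  e <- sum(d1 * w); f <- sum(d2 * w)
  det <- a * c - b * b
  if (det <= 1e-14 * a * c)
    return(list(p1 = NULL, p2 = NULL, ill = TRUE))
  s <- (c * e - b * f) / det
  t <- (b * e - a * f) / det
  list(p1 = o1 + s * d1, p2 = o2 + t * d2, ill = FALSE)
}

#' Build one lumen cross-section patch
#'
#' For a centerline parameter t, intersects each view's 2D centerline normal
#' with its two vessel borders, lifts the intersections onto the positioned
#' detector, and for each lifted point finds the point where the silhouette
#' X-ray grazes the vessel: the foot, on the X-ray, of the common
#' perpendicular between the ray and the centerline tangent line.  The feet
#' are projected into the normal-binormal plane of the centerline frame,
#' giving two boundary points per contributing view.
#'
#' @param t centerline parameter in [0, 1].
#' @param branch a \code{branch_centerline}.
#' @param views list of per-view lists with elements \code{c2d} (2D
#'   centerline polyline, mm), \code{borders} (list of two border
#'   polylines), \code{pose} (a \code{gantry_pose}) and \code{s_of_t}
#'   (function mapping curve parameter to 2D arc parameter).
#' @param search_halfwidth maximum normal-border intersection distance (mm).
#' @return object of class \code{cross_section_patch}: \code{center},
#'   \code{t}, \code{frame} (list T, N, B), \code{points2d} (boundary points
#'   in the N-B plane, polar-sorted), \code{complete},
#'   \code{ill_conditioned}.
#' @export
build_patch <- function(t, branch, views, search_halfwidth = 10) {
  C <- as.numeric(eval_bspline(branch$curve, t))
  d1 <- as.numeric(eval_bspline(branch$curve, t, 1))
  Tv <- .normalize(d1)
  fi <- which.min(abs(branch$frames$ts - t))
  # re-transport the stored frame onto the exact tangent at t
  Nv <- branch$frames$N[fi, ]
  Nv <- .normalize(Nv - sum(Nv * Tv) * Tv)
  Bv <- .normalize(cross3(Tv, Nv))

  pts <- NULL
  complete <- TRUE; ill <- FALSE
  dirs <- list()
  for (vw in views) {
    s <- vw$s_of_t(t)
    p <- as.numeric(polyline_point(vw$c2d, s))
    tg <- as.numeric(polyline_tangent(vw$c2d, s))
    nr <- c(-tg[2], tg[1])
    fr <- .pose_frame(vw$pose)
    dirs[[length(dirs) + 1]] <- .normalize(C - fr$F)
    for (b in vw$borders) {
      x <- polyline_line_intersect(b, p, nr, search_halfwidth)
      if (is.null(x)) { complete <- FALSE; next }
      Pw <- detector_to_world(x, vw$pose)
      cp <- .closest_points(fr$F, Pw - fr$F, C, Tv)
      if (cp$ill) { ill <- TRUE; next }
      rel <- cp$p1 - C                      # foot on the silhouette ray
      pts <- rbind(pts, c(sum(rel * Nv), sum(rel * Bv)))
    }
  }
  if (length(dirs) >= 2) {
    ang <- acos(pmin(1, abs(sum(dirs[[1]] * dirs[[2]]))))
    if (ang < .deg(1)) ill <- TRUE          # views indistinguishable
  }
  if (!is.null(pts)) {
    ord <- order(atan2(pts[, 2] - mean(pts[, 2]), pts[, 1] - mean(pts[, 1])))
    pts <- pts[ord, , drop = FALSE]
  }
  structure(list(center = C, t = t, frame = list(T = Tv, N = Nv, B = Bv),
                 points2d = pts, complete = complete, ill_conditioned = ill),
            class = "cross_section_patch")
}

#' Fit a lumen cross-section to in-plane boundary points
#'
#' Circle: algebraic least squares.  Ellipse: direct least-squares conic
#' constrained to an ellipse.  Polygon: points converted to polar
#' coordinates about their centroid and sorted in circular direction.
#' With two views (four points) the circle is recommended; ellipses need at
#' least three views (five points) and polygons at least six views.
#'
#' @param pts m x 2 matrix of boundary points in the normal-binormal plane.
#' @param mode "circle", "ellipse" or "polygon".
#' @return list describing the fit; class \code{cross_section_fit} with
#'   \code{mode} and mode-specific fields (circle: \code{center},
#'   \code{radius}; ellipse: \code{center}, \code{axes}, \code{angle};
#'   polygon: \code{points}).
#' @export
fit_cross_section <- function(pts, mode = c("circle", "ellipse", "polygon")) {
  mode <- match.arg(mode)
  pts <- as.matrix(pts)
  m <- nrow(pts)
  need <- c(circle = 3, ellipse = 5, polygon = 6)[mode]
  if (m < need)
    stop(sprintf(paste0("%s fit needs at least %d points; two views give 4 ",
                        "(use circle), three or more views allow an ellipse, ",
                        "six or more a polygon"), mode, need))
  x <- pts[, 1]; y <- pts[, 2]
  if (mode == "circle") {
    A <- cbind(2 * x, 2 * y, 1)
    qrA <- qr(A)
    if (qrA$rank < 3) stop("degenerate circle fit: points are collinear")
    sol <- qr.coef(qrA, x^2 + y^2)
    r2 <- sol[3] + sol[1]^2 + sol[2]^2
    if (r2 <= 0) stop("degenerate circle fit")
    out <- list(mode = "circle", center = c(sol[1], sol[2]), radius = sqrt(r2))
  } else if (mode == "ellipse") {
    out <- c(list(mode = "ellipse"), .fit_ellipse(x, y))
  } else {
    ctr <- colMeans(pts)
    ang <- atan2(y - ctr[2], x - ctr[1])
    ord <- order(ang)
    out <- list(mode = "polygon", center = ctr,
                points = pts[ord, , drop = FALSE], angles = ang[ord])
  }
  class(out) <- "cross_section_fit"
  out
}

# direct least-squares ellipse (Fitzgibbon-style generalized eigenproblem)
.fit_ellipse <- function(x, y) {
  x0 <- mean(x); y0 <- mean(y)
  xs <- x - x0; ys <- y - y0
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  a1 <- NULL
  for (j in seq_len(3)) {
    v <- Re(ev$vectors[, j])
    cond <- 4 * v[1] * v[3] - v[2]^2
    if (cond > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stop("no ellipse fits these points")
  a <- c(a1, as.numeric(Tm %*% a1))           # A B C D E F on centred coords
  A <- a[1]; B <- a[2]; C <- a[3]; D <- a[4]; E <- a[5]; F <- a[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  r1 <- -sqrt(num * ((A + C) + s)) / den
  r2 <- -sqrt(num * ((A + C) - s)) / den
  theta <- 0.5 * atan2(-B, C - A)
  list(center = c(cx + x0, cy + y0),
       axes = sort(c(r1, r2), decreasing = TRUE), angle = theta)
}

# sample w boundary points of a fitted cross-section at uniform polar angles
.sample_fit <- function(fit, w) {
  th <- 2 * pi * (seq_len(w) - 1) / w
  if (fit$mode == "circle") {
    cbind(fit$center[1] + fit$radius * cos(th),
          fit$center[2] + fit$radius * sin(th))
  } else if (fit$mode == "ellipse") {
    ca <- cos(fit$angle); sa <- sin(fit$angle)
    xe <- fit$axes[1] * cos(th); ye <- fit$axes[2] * sin(th)
    cbind(fit$center[1] + ca * xe - sa * ye,
          fit$center[2] + sa * xe + ca * ye)
  } else {
    # polar interpolation of the star-shaped polygon about its centroid
    ang <- fit$angles
    r <- sqrt(rowSums(sweep(fit$points, 2, fit$center)^2))
    ang <- c(ang, ang[1] + 2 * pi); r <- c(r, r[1])
    ri <- approx(ang, r, xout = ifelse(th < ang[1], th + 2 * pi, th))$y
    cbind(fit$center[1] + ri * cos(th), fit$center[2] + ri * sin(th))
  }
}

#' Assemble a branch lumen surface from ordered cross-section patches
#'
#' Each fitted patch is sampled with \code{w} points at uniform polar angles
#' in its normal-binormal plane (shared angles across patches avoid
#' twisting), lifted to 3D, and interpolated by a tensor-product B-spline
#' surface: closed (periodic) of order \code{l} in the circular direction,
#' clamped of order \code{k} in the longitudinal direction with the patch
#' parameters as interpolation sites.  The surface passes through every
#' sampled boundary point.
#'
#' @param patches list of \code{cross_section_patch}es with fits attached
#'   (see \code{\link{fit_cross_section}}; element \code{fit}).
#' @param w circular control/sample count (default 16).
#' @param k,l longitudinal / circular orders (default cubic, 4).
#' @return object of class \code{branch_surface}: \code{control}
#'   (q x w x 3 array), \code{uknots}, \code{k}, \code{l}, \code{w},
#'   \code{u_sites}, \code{centers}, \code{frames}.
#' @export
assemble_surface <- function(patches, w = 16, k = 4, l = 4) {
  q <- length(patches)
  stopifnot(q >= 2)
  rings <- array(0, c(q, w, 3))
  centers <- matrix(0, q, 3)
  for (i in seq_len(q)) {
    p <- patches[[i]]
    if (is.null(p$fit)) stop("patch has no cross-section fit attached")
    r2 <- .sample_fit(p$fit, w)
    centers[i, ] <- p$center
    rings[i, , ] <- matrix(p$center, w, 3, byrow = TRUE) +
      outer(r2[, 1], p$frame$N) + outer(r2[, 2], p$frame$B)
  }
  # skinning: periodic interpolation in v, clamped interpolation in u
  vctrl <- array(0, c(q, w, 3))
  for (i in seq_len(q)) vctrl[i, , ] <- periodic_interp_ord(rings[i, , ], l)
  u_sites <- vapply(patches, `[[`, numeric(1), "t")
  u_sites <- (u_sites - u_sites[1]) / (u_sites[q] - u_sites[1])
  uknots <- .clamped_knots(u_sites, q, k)
  Bu <- bspline_basis(u_sites, uknots, k)
  control <- array(0, c(q, w, 3))
  for (j in seq_len(w)) control[, j, ] <- solve(Bu, vctrl[, j, ])
  structure(list(control = control, uknots = uknots, k = k, l = l, w = w,
                 u_sites = u_sites, centers = centers,
                 patches = patches),
            class = "branch_surface")
}

# periodic interpolation with configurable order
periodic_interp_ord <- function(y, l) {
  w <- nrow(y)
  A <- periodic_basis((seq_len(w) - 1) / w, w, l)
  solve(A, y)
}

#' Evaluate a branch surface on a (u, v) grid
#'
#' @param surf a \code{branch_surface}.
#' @param u,v numeric vectors; u in [0, 1] (longitudinal), v in [0, 1)
#'   (circular, periodic).
#' @return array length(u) x length(v) x 3.
#' @export
eval_surface <- function(surf, u, v) {
  Bu <- bspline_basis(u, surf$uknots, surf$k)
  Bv <- periodic_basis(v, surf$w, surf$l)
  out <- array(0, c(length(u), length(v), 3))
  for (d in 1:3) out[, , d] <- Bu %*% surf$control[, , d] %*% t(Bv)
  out
}

#' Tessellate a branch surface into a triangle mesh
#'
#' @param surf a \code{branch_surface}.
#' @param nu,nv longitudinal / circular tessellation density.
#' @return list with \code{vertices} (n x 3) and \code{faces} (m x 3,
#'   1-based, outward-oriented).
#' @export
surface_to_mesh <- function(surf, nu = 60, nv = 32) {
  u <- seq(0, 1, length.out = nu)
  v <- (seq_len(nv) - 1) / nv
  G <- eval_surface(surf, u, v)
  verts <- matrix(0, nu * nv, 3)
  for (d in 1:3) verts[, d] <- as.numeric(t(G[, , d]))   # v fastest
  idx <- function(i, j) (i - 1) * nv + ((j - 1) %% nv) + 1
  faces <- NULL
  for (i in seq_len(nu - 1)) {
    for (j in seq_len(nv)) {
      a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      faces <- rbind(faces, c(a, b, c), c(a, c, d))
    }
  }
  .orient_outward(list(vertices = verts, faces = faces))
}

# consistent winding assumed; flip all faces if they point inward on average
.orient_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], ]; b <- V[F[, 2], ]; c <- V[F[, 3], ]
  n <- cbind((b[,2]-a[,2])*(c[,3]-a[,3]) - (b[,3]-a[,3])*(c[,2]-a[,2]),
             (b[,3]-a[,3])*(c[,1]-a[,1]) - (b[,1]-a[,1])*(c[,3]-a[,3]),
             (b[,1]-a[,1])*(c[,2]-a[,2]) - (b[,2]-a[,2])*(c[,1]-a[,1]))
  ctr <- matrix(colMeans(V), nrow(F), 3, byrow = TRUE)
  outward <- rowSums(n * ((a + b + c) / 3 - ctr))
  if (mean(sign(outward)) < 0) mesh$faces <- F[, c(1, 3, 2)]
  mesh
}

#' @export
print.branch_surface <- function(x, ...) {
  cat(sprintf("Branch lumen surface: %d x %d control net, orders (%d, %d)\n",
              dim(x$control)[1], x$w, x$k, x$l))
  invisible(x)
}
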