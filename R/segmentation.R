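# ---------------------------------------------------------------------------
# Semi-automatic 2D extraction: multiscale Hessian (Frangi-type) vesselness,
# fast-marching centerline tracking from user seeds, tree decomposition and
# Dijkstra border detection.  Images are matrices (rows = image rows);
# points are (x = column, y = row), 1-based, at sub-pixel precision.
# ---------------------------------------------------------------------------

.gauss_kernels <- function(sigma) {
  r <- max(2, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  list(g = g, g1 = g1, g2 = g2)
}

#' Multiscale Hessian vesselness filter
#'
#' Tubularity response of dark vessels on a bright background: the image is
#' inverted, smoothed at each scale, and the Hessian eigenvalues are
#' combined into the classic ridge measure
#' \code{exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))} for negative
#' principal curvature, taking the maximum over scales and normalizing to
#' [0, 1].  The structureness cutoff \code{c} is relative to the strongest
#' Hessian norm at each scale, so the response is invariant to intensity
#' offsets.
#'
#' @param img image matrix (rows = image rows), darker = vessel.
#' @param scales Gaussian scales in pixels (default \code{seq(2, 6, 0.5)}).
#' @param beta blobness sensitivity (default 0.5).
#' @param c_rel relative structureness sensitivity (default 0.1).
#' @return matrix of the same size with values in [0, 1].
#' @export
vesselness <- function(img, scales = seq(2, 6, by = 0.5),
                       beta = 0.5, c_rel = 0.1) {
  if (length(dim(img)) != 2) stop("vesselness needs a 2D image")
  work <- max(img) - img                      # bright ridges
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    k <- .gauss_kernels(s)
    Lxx <- cx_conv_sep(work, k$g2, k$g) * s^2   # x = columns
    Lyy <- cx_conv_sep(work, k$g, k$g2) * s^2
    Lxy <- cx_conv_sep(work, k$g1, k$g1) * s^2
    tr2 <- (Lxx + Lyy) / 2
    det2 <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
    mu1 <- tr2 + det2; mu2 <- tr2 - det2
    swap <- abs(mu1) > abs(mu2)               # |lambda1| <= |lambda2|
    l1 <- ifelse(swap, mu2, mu1); l2 <- ifelse(swap, mu1, mu2)
    S <- sqrt(l1^2 + l2^2)
    smax <- max(S)
    if (smax == 0) next
    cpar <- c_rel * smax
    Rb <- ifelse(l2 != 0, l1 / l2, 0)
    V <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cpar^2)))
    V[l2 > 0] <- 0                            # bright ridge: lambda2 < 0
    out <- pmax(out, V)
  }
  m <- max(out)
  if (m > 0) out <- out / m
  out
}

#' Track centerlines by fast marching from an inlet seed
#'
#' Solves the Eikonal arrival-time field from the inlet with the supplied
#' speed map (e.g. \code{1e-3 + vesselness(img)}) and backtracks each
#' outlet to the source by steepest descent on the arrival time.
#'
#' @param speed matrix of positive propagation speeds.
#' @param inlet c(x, y) seed, 1-based pixels.
#' @param outlets list of c(x, y) end points (or a single point).
#' @return list of paths, each an n x 2 matrix (x, y) ordered from the
#'   inlet to the outlet; unreachable outlets yield NULL with a warning.
#' @export
track_centerline <- function(speed, inlet, outlets) {
  stopifnot(all(speed > 0))
  if (!is.list(outlets)) outlets <- list(outlets)
  Tmap <- cx_fmm(speed, round(inlet[2]), round(inlet[1]))
  nr <- nrow(speed); nc <- ncol(speed)
  lapply(outlets, function(o) {
    i <- round(o[2]); j <- round(o[1])
    if (!is.finite(Tmap[i, j])) {
      warning(sprintf("outlet (%g, %g) unreachable from the inlet", o[1], o[2]))
      return(NULL)
    }
    path <- matrix(c(j, i), 1, 2)
    repeat {
      if (Tmap[i, j] == 0) break
      win_i <- max(1, i - 1):min(nr, i + 1)
      win_j <- max(1, j - 1):min(nc, j + 1)
      sub <- Tmap[win_i, win_j, drop = FALSE]
      k <- arrayInd(which.min(sub), dim(sub))
      ni <- win_i[k[1]]; nj <- win_j[k[2]]
      if (Tmap[ni, nj] >= Tmap[i, j]) break   # plateau guard
      i <- ni; j <- nj
      path <- rbind(path, c(j, i))
    }
    path[rev(seq_len(nrow(path))), , drop = FALSE]
  })
}

#' Decompose inlet-to-outlet paths into unique branches
#'
#' Paths that share a prefix (within a spatial tolerance) are split at their
#' divergence points: the longest common prefixes become shared parent
#' branches and the divergence points become bifurcations, so that the
#' branch set covers every input path exactly once.
#'
#' @param paths list of n x 2 path matrices sharing the inlet.
#' @param tol divergence tolerance in pixels (default 1.5).
#' @return list of class \code{vessel_tree_2d}: \code{branches} (list of
#'   polylines), \code{parent} (index vector, NA for the root),
#'   \code{bifurcations} (list of list(point, parent, children)),
#'   \code{inlet}.
#' @export
decompose_tree <- function(paths, tol = 1.5) {
  paths <- Filter(Negate(is.null), paths)
  stopifnot(length(paths) >= 1)
  branches <- list(); parent_of <- integer(0); bifs <- list()

  recurse <- function(group, offset, parent_idx) {
    if (length(group) == 1) {
      branches[[length(branches) + 1]] <<- group[[1]]
      parent_of[length(branches)] <<- parent_idx
      return(invisible(NULL))
    }
    lens <- vapply(group, nrow, integer(1))
    L <- 1
    while (L < min(lens)) {
      ref <- group[[1]][L + 1, ]
      ok <- all(vapply(group[-1], function(p)
        sqrt(sum((p[L + 1, ] - ref)^2)) <= tol, logical(1)))
      if (!ok) break
      L <- L + 1
    }
    branches[[length(branches) + 1]] <<- group[[1]][seq_len(L), , drop = FALSE]
    me <- length(branches)
    parent_of[me] <<- parent_idx
    # cluster the diverging continuations by their next point
    rest <- lapply(group, function(p) p[L:nrow(p), , drop = FALSE])
    keyp <- t(vapply(rest, function(p) p[min(2, nrow(p)), ], numeric(2)))
    groups <- list()
    for (i in seq_along(rest)) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        if (sqrt(sum((keyp[i, ] - keyp[groups[[g]][1], ])^2)) <= tol) {
          groups[[g]] <- c(groups[[g]], i); placed <- TRUE; break
        }
      }
      if (!placed) groups[[length(groups) + 1]] <- i
    }
    kids_first <- integer(0)
    for (g in groups) {
      before <- length(branches)
      recurse(rest[g], offset + L - 1, me)
      kids_first <- c(kids_first, before + 1)
    }
    bifs[[length(bifs) + 1]] <<- list(point = group[[1]][L, ],
                                      parent = me, children = kids_first)
    invisible(NULL)
  }
  recurse(paths, 0, NA_integer_)
  structure(list(branches = branches, parent = parent_of,
                 bifurcations = bifs, inlet = paths[[1]][1, ]),
            class = "vessel_tree_2d")
}

#' @export
print.vessel_tree_2d <- function(x, ...) {
  cat(sprintf("2D vessel tree: %d branches, %d bifurcations\n",
              length(x$branches), length(x$bifurcations)))
  invisible(x)
}

#' Detect the two vessel borders along a centerline
#'
#' Enhances edges with a Sobel gradient-magnitude operator, converts the
#' image into an 8-connected graph whose node cost is inversely related to
#' edge strength, picks the strongest edge response along the inlet and
#' outlet centerline normals on each side as border end-points, removes
#' ("unfastens") the nodes along the centerline so no path can cross it,
#' and extracts each border as the Dijkstra shortest path between its
#' end-points.
#'
#' @param img image matrix.
#' @param centerline n x 2 (x, y) polyline in pixels.
#' @param search_halfwidth end-point search half-width in pixels.
#' @return list of class \code{border_pair}: \code{left}, \code{right}
#'   (polylines ordered and parameterized consistently with the
#'   centerline).
#' @export
detect_borders <- function(img, centerline, search_halfwidth = 20) {
  sob <- c(1, 2, 1) / 4; der <- c(-1, 0, 1) / 2
  gx <- cx_conv_sep(img, der, sob)
  gy <- cx_conv_sep(img, sob, der)
  mag <- sqrt(gx^2 + gy^2)
  cost <- 1 / (0.01 * max(mag) + mag)

  nr <- nrow(img); nc <- ncol(img)
  blocked <- matrix(0L, nr, nc)
  dense <- resample_polyline(centerline, 4 * nrow(centerline))
  for (i in seq_len(nrow(dense))) {
    r <- round(dense[i, 2]); cl <- round(dense[i, 1])
    if (r >= 1 && r <= nr && cl >= 1 && cl <= nc) blocked[r, cl] <- 1L
  }

  endpoint <- function(s, side) {
    p <- as.numeric(polyline_point(centerline, s))
    tg <- as.numeric(polyline_tangent(centerline, s))
    nrm <- c(-tg[2], tg[1]) * side
    best <- NULL; bv <- -Inf
    for (d in seq(1.5, search_halfwidth, by = 0.5)) {
      q <- p + d * nrm
      r <- round(q[2]); cl <- round(q[1])
      if (r < 1 || r > nr || cl < 1 || cl > nc) break
      if (blocked[r, cl]) next
      if (mag[r, cl] > bv) { bv <- mag[r, cl]; best <- c(cl, r) }
    }
    if (is.null(best)) stop("no border edge found along the centerline normal")
    best
  }

  trace_side <- function(side) {
    a <- endpoint(0, side); b <- endpoint(1, side)
    path <- cx_grid_dijkstra(cost, blocked, a[2], a[1], b[2], b[1])
    cbind(path[, 2], path[, 1])                # back to (x, y)
  }
  structure(list(left = trace_side(1), right = trace_side(-1)),
            class = "border_pair")
}
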