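# ---------------------------------------------------------------------------
# Structured O-grid quad/hex meshing of single branches and coronary trees.
# A cross-section patch has 2v + 1 nodes (center, inner ring at 45% of the
# outer radius, outer ring) and 3v/2 quads (v/2 core + v ring); stacking two
# successive patches yields one layer of 3v/2 hexahedra.
# ---------------------------------------------------------------------------

# local connectivity of one patch: rows into the node list
# node rows: 1 = center, 2..(v+1) = inner_j, (v+2)..(2v+1) = outer_j
patch_quads <- function(v) {
  if (v %% 4 != 0 || v < 4)
    stop("circular subdivision v must be a positive multiple of 4")
  inner <- function(j) 1 + ((j - 1) %% v) + 1
  outer <- function(j) 1 + v + ((j - 1) %% v) + 1
  core <- t(vapply(seq_len(v / 2), function(i) {
    j <- 2 * i - 1
    c(1, inner(j), inner(j + 1), inner(j + 2))
  }, numeric(4)))
  ring <- t(vapply(seq_len(v), function(j) {
    c(inner(j), outer(j), outer(j + 1), inner(j + 1))
  }, numeric(4)))
  rbind(core, ring)
}

#' Build one structured O-grid quadrilateral patch
#'
#' The patch pattern of a vessel cross-section: a central node, an inner
#' ring placed at a fixed fraction (default 45%) of the way from the center
#' to the outer contour, and the outer contour itself, subdivided into
#' \code{v/2} core quads around the center plus \code{v} ring quads.
#'
#' @param center 3-vector, the cross-section center.
#' @param ring m x 3 matrix of outer-contour points in circular order
#'   (resampled to \code{v} points if m differs from v).
#' @param v circular subdivision, a multiple of 4.
#' @param inner_ratio radial position of the inner ring (default 0.45).
#' @return object of class \code{quad_patch}: \code{nodes}
#'   ((2v+1) x 3), \code{quads} (3v/2 x 4 row indices), \code{v}.
#' @export
make_patch <- function(center, ring, v = 8, inner_ratio = 0.45) {
  ring <- as.matrix(ring)
  if (nrow(ring) != v) {
    closed <- rbind(ring, ring[1, ])
    ring <- resample_polyline(closed, v + 1)[seq_len(v), , drop = FALSE]
  }
  inner <- matrix(center, v, 3, byrow = TRUE) * (1 - inner_ratio) +
    ring * inner_ratio
  nodes <- rbind(matrix(center, 1, 3), inner, ring)
  structure(list(nodes = nodes, quads = patch_quads(v), v = v),
            class = "quad_patch")
}

#' Sweep a stack of quadrilateral patches into a hexahedral block
#'
#' Two successive patches bound one layer of hexahedra whose faces are the
#' patches' quads; a stack of q patches gives (q-1) * 3v/2 elements.
#'
#' @param patches list of \code{quad_patch} objects sharing \code{v} and
#'   node ordering.
#' @return object of class \code{hex_mesh}: \code{nodes} (n x 3),
#'   \code{hexes} (m x 8, 1-based; first four nodes the quad on the earlier
#'   patch, last four the same quad on the later patch).
#' @export
sweep_hexes <- function(patches) {
  v <- patches[[1]]$v
  if (!all(vapply(patches, `[[`, numeric(1), "v") == v))
    stop("all patches in a sweep must share the circular subdivision v")
  q <- length(patches)
  npp <- 2 * v + 1
  nodes <- do.call(rbind, lapply(patches, `[[`, "nodes"))
  quads <- patches[[1]]$quads
  hexes <- NULL
  for (i in seq_len(q - 1)) {
    off0 <- (i - 1) * npp; off1 <- i * npp
    hexes <- rbind(hexes, cbind(quads + off0, quads + off1))
  }
  structure(list(nodes = nodes, hexes = hexes, v = v), class = "hex_mesh")
}

# corner adjacency of the 8-node hex (bottom quad 1-4 ccw, top 5-8):
# at each corner the three adjacent corners, ordered right-handed
.hex_adj <- rbind(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                  c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))

#' Scaled-Jacobian quality of a hexahedral mesh
#'
#' With \code{at = "corners"} (the default verification metric): for every
#' element and every one of its 8 corners, the determinant of the three
#' normalized edge vectors leaving that corner; the element value is the
#' minimum over corners.  1 is the ideal cube, 0 a degenerate corner,
#' negative an inverted element.  Note that the O-grid patch pattern itself
#' bounds this metric: the inner-ring corners of the core quads subtend
#' 135 degrees on an ideal circular section, so a perfect cylinder mesh
#' scores sin(135 deg) = 0.7071 there.  With \code{at = "centroid"} the
#' trilinear map's normalized Jacobian is evaluated at the element center
#' (the single-integration-point metric common in FEA), which is insensitive
#' to that corner angle.
#'
#' @param mesh a \code{hex_mesh}.
#' @param at "corners" or "centroid".
#' @return list with \code{jacobian} (per-element scaled Jacobian),
#'   \code{min}, \code{mean} and a \code{histogram}.
#' @export
mesh_quality <- function(mesh, at = c("corners", "centroid")) {
  at <- match.arg(at)
  stopifnot(nrow(mesh$hexes) > 0)
  sj <- apply(mesh$hexes, 1, function(h) {
    X <- mesh$nodes[h, , drop = FALSE]
    if (at == "corners") {
      m <- Inf
      for (c0 in 1:8) {
        E <- X[.hex_adj[c0, ], , drop = FALSE] - rep(X[c0, ], each = 3)
        ln <- sqrt(rowSums(E^2))
        if (any(ln == 0)) { m <- min(m, 0); next }
        m <- min(m, det(E / ln))
      }
      m
    } else {
      # trilinear shape-function derivatives at the element center
      J <- rbind((X[2, ] + X[3, ] + X[6, ] + X[7, ] -
                  X[1, ] - X[4, ] - X[5, ] - X[8, ]) / 4,
                 (X[3, ] + X[4, ] + X[7, ] + X[8, ] -
                  X[1, ] - X[2, ] - X[5, ] - X[6, ]) / 4,
                 (X[5, ] + X[6, ] + X[7, ] + X[8, ] -
                  X[1, ] - X[2, ] - X[3, ] - X[4, ]) / 4)
      ln <- sqrt(rowSums(J^2))
      if (any(ln == 0)) 0 else det(J / ln)
    }
  })
  list(jacobian = sj, min = min(sj), mean = mean(sj), at = at,
       histogram = hist(sj, breaks = seq(-1, 1, by = 0.1), plot = FALSE))
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hexahedral mesh: %d nodes, %d elements (v = %d)\n",
              nrow(x$nodes), nrow(x$hexes), x$v))
  invisible(x)
}

#' @export
summary.hex_mesh <- function(object, ...) {
  q <- mesh_quality(object)
  cat(sprintf("Hexahedral mesh: %d nodes, %d elements\n",
              nrow(object$nodes), nrow(object$hexes)))
  cat(sprintf("Scaled Jacobian: min %.4f, mean %.4f\n", q$min, q$mean))
  invisible(q)
}

#' @export
plot.hex_mesh <- function(x, ...) {
  q <- mesh_quality(x)
  graphics::hist(q$jacobian, breaks = seq(-1, 1, by = 0.05),
                 main = "Element quality", xlab = "scaled Jacobian", ...)
  invisible(q)
}

# face corner table of the 8-node hex
.hex_faces <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                    c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))

#' Face-incidence audit of a hexahedral mesh
#'
#' Counts, for every quad face, how many elements contain it.  A conforming
#' watertight mesh has every face on exactly 1 (boundary) or 2 (interior)
#' elements.
#'
#' @param mesh a \code{hex_mesh}.
#' @return table of face multiplicities.
#' @export
mesh_face_incidence <- function(mesh) {
  keys <- character(nrow(mesh$hexes) * 6)
  r <- 1
  for (e in seq_len(nrow(mesh$hexes))) {
    h <- mesh$hexes[e, ]
    for (f in 1:6) {
      keys[r] <- paste(sort(h[.hex_faces[f, ]]), collapse = "-")
      r <- r + 1
    }
  }
  table(table(keys))
}

# ---------------------------------------------------------------------------
# coronary tree container and frame smoothing
# ---------------------------------------------------------------------------

#' Assemble reconstructed branches into a coronary tree
#'
#' @param branches list of branch entries; each a list with elements
#'   \code{centerline} (a \code{branch_centerline}) and optionally
#'   \code{surface} (a \code{branch_surface}).
#' @param parent integer vector: index of each branch's parent (NA for the
#'   root).  Each bifurcation must have exactly one parent and two children.
#' @return object of class \code{coronary_tree}.
#' @export
coronary_tree <- function(branches, parent) {
  stopifnot(length(parent) == length(branches), sum(is.na(parent)) == 1)
  kids <- lapply(seq_along(branches), function(i) which(parent == i))
  if (any(vapply(kids, length, integer(1)) %in% c(1) |
          vapply(kids, length, integer(1)) > 2))
    stop("each bifurcation must have exactly two child branches")
  structure(list(branches = branches, parent = parent, children = kids),
            class = "coronary_tree")
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("Coronary tree: %d branches, %d bifurcations\n",
              length(x$branches),
              sum(vapply(x$children, length, integer(1)) == 2)))
  invisible(x)
}

#' Smooth the moving frames of a tree across its bifurcations
#'
#' Re-seeds every child branch's rotation-minimizing frame sequence from the
#' end-trihedron of its parent: the parent's end normal is carried over the
#' minimal rotation that maps the parent's end tangent onto the child's
#' start tangent, and then propagated along the child.  Idempotent.
#'
#' @param tree a \code{coronary_tree}.
#' @return the tree with updated \code{frames} in every branch centerline.
#' @export
smooth_trihedrons <- function(tree) {
  root <- which(is.na(tree$parent))
  order_bfs <- root
  queue <- tree$children[[root]]
  while (length(queue)) {
    order_bfs <- c(order_bfs, queue[1])
    queue <- c(queue[-1], tree$children[[queue[1]]])
  }
  for (i in order_bfs) {
    br <- tree$branches[[i]]$centerline
    p <- tree$parent[i]
    if (is.na(p)) {
      ts <- br$frames$ts
      tree$branches[[i]]$centerline$frames <-
        frenet_frames(br$curve, ts, method = "rmf")
      next
    }
    pf <- tree$branches[[p]]$centerline$frames
    np <- nrow(pf$T)
    Tp <- pf$T[np, ]; Np <- pf$N[np, ]
    Tc <- .normalize(as.numeric(eval_bspline(br$curve, 0, 1)))
    ax <- cross3(Tp, Tc)
    s <- sqrt(sum(ax^2)); cth <- sum(Tp * Tc)
    Nseed <- if (s < 1e-12) Np else {
      ax <- ax / s
      # Rodrigues rotation of the parent end-normal
      Np * cth + cross3(ax, Np) * s + ax * sum(ax * Np) * (1 - cth)
    }
    ts <- br$frames$ts
    tree$branches[[i]]$centerline$frames <-
      frenet_frames(br$curve, ts, method = "rmf", seed_normal = Nseed)
  }
  tree
}

# ---------------------------------------------------------------------------
# single-branch meshing from a lumen surface
# ---------------------------------------------------------------------------

# ring stack of one branch: outer contours sampled from the NURBS surface at
# the frame-consistent circular origin, with an optional linear twist (rad)
# distributed along the branch to honour junction alignment at both ends.
.branch_rings <- function(surface, n_long, v, twist = c(0, 0)) {
  u <- seq(0, 1, length.out = n_long + 1)
  phi <- twist[1] + (twist[2] - twist[1]) * u
  rings <- vector("list", n_long + 1)
  uc <- seq(0, 1, length.out = nrow(surface$centers))
  for (j in seq_along(u)) {
    vv <- ((seq_len(v) - 1) / v + phi[j] / (2 * pi)) %% 1
    G <- eval_surface(surface, u[j], vv)
    outer <- matrix(G[1, , ], v, 3)
    ctr <- vapply(1:3, function(d) approx(uc, surface$centers[, d],
                                          xout = u[j])$y, numeric(1))
    rings[[j]] <- list(center = ctr, outer = outer)
  }
  rings
}

# emit patches for a ring stack and sweep them
.rings_to_mesh <- function(rings, v, inner_ratio = 0.45) {
  patches <- lapply(rings, function(r) make_patch(r$center, r$outer, v,
                                                  inner_ratio))
  sweep_hexes(patches)
}

#' Structured hexahedral mesh of a single branch
#'
#' Samples the branch lumen surface into \code{n_long + 1} cross-section
#' patches of circular subdivision \code{v} and sweeps them into hexahedra.
#'
#' @param surface a \code{branch_surface}.
#' @param n_long longitudinal subdivisions (default 10).
#' @param v circular subdivisions, multiple of 4 (default 8).
#' @param inner_ratio inner-ring radial fraction (default 0.45).
#' @return a \code{hex_mesh}.
#' @export
mesh_branch <- function(surface, n_long = 10, v = 8, inner_ratio = 0.45) {
  .rings_to_mesh(.branch_rings(surface, n_long, v), v, inner_ratio)
}
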