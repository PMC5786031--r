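# ---------------------------------------------------------------------------
# Synthetic ground-truth phantoms: 3D tube trees with known radii/stenoses,
# their exact perspective projections (centerlines and true silhouette
# borders) under known gantry poses, optional rasterized frames, and frame
# sequences with controllable cardiac phase shift.
# ---------------------------------------------------------------------------

#' Straight-branch generator
#' @param start 3-vector (mm). @param dir direction (normalized internally).
#' @param length branch length, mm. @param radius nominal tube radius, mm.
#' @param stenosis optional list(depth, at, width): fractional depth in
#'   [0, 1), center (arc fraction) and Gaussian width (arc fraction).
#' @return branch generator list.
#' @export
branch_line <- function(start, dir, length, radius, stenosis = NULL) {
  dir <- .normalize(dir)
  list(type = "line",
       fn = function(s) {
         outer(s * length, dir) + matrix(start, length(s), 3, byrow = TRUE)
       },
       radius = .radius_fun(radius, stenosis), length = length)
}

#' Circular-arc branch generator
#' @param start 3-vector; \code{dir} initial tangent; \code{axis} rotation
#'   axis (defines the bend plane, need not be exactly perpendicular to
#'   dir); \code{bend_radius} mm; \code{angle} swept arc, degrees.
#' @inheritParams branch_line
#' @return branch generator list.
#' @export
branch_arc <- function(start, dir, axis, bend_radius, angle, radius,
                       stenosis = NULL) {
  dir <- .normalize(dir)
  axis <- .normalize(axis - sum(axis * dir) * dir)
  n0 <- .normalize(cross3(axis, dir))       # toward the bend center
  O <- start + bend_radius * n0
  ang <- .deg(angle)
  list(type = "arc",
       fn = function(s) {
         phi <- s * ang
         sweep(outer(cos(phi), start - O) + outer(sin(phi), bend_radius * dir),
               2, O, "+")
       },
       radius = .radius_fun(radius, stenosis),
       length = bend_radius * ang)
}

#' Helical branch generator
#' @inheritParams branch_arc
#' @param helix_radius,pitch helix geometry, mm (pitch per full turn).
#' @param turns number of turns.
#' @export
branch_helix <- function(start, axis, helix_radius, pitch, turns, radius,
                         stenosis = NULL) {
  axis <- .normalize(axis)
  u <- if (abs(axis[3]) < 0.9) .normalize(cross3(axis, c(0, 0, 1)))
       else .normalize(cross3(axis, c(0, 1, 0)))
  w <- cross3(axis, u)
  ang <- 2 * pi * turns
  list(type = "helix",
       fn = function(s) {
         phi <- s * ang
         sweep(outer(cos(phi) - 1, helix_radius * u) +
               outer(sin(phi), helix_radius * w) +
               outer(s * turns * pitch, axis), 2, start, "+")
       },
       radius = .radius_fun(radius, stenosis),
       length = sqrt((2 * pi * helix_radius)^2 + pitch^2) * turns)
}

.radius_fun <- function(radius, stenosis) {
  if (is.null(stenosis)) return(function(s) rep(radius, length(s)))
  stopifnot(stenosis$depth >= 0, stenosis$depth < 1)
  function(s) radius * (1 - stenosis$depth *
                          exp(-((s - stenosis$at) / stenosis$width)^2 / 2))
}

#' Phantom study specification
#'
#' @param branches list of branch generators (\code{\link{branch_line}},
#'   \code{\link{branch_arc}}, \code{\link{branch_helix}}).
#' @param parent integer vector of parent branch indices (NA for root).
#' @param poses list of \code{\link{gantry_pose}} objects, one per view
#'   (the injected misalignments of the poses are part of the ground truth).
#' @param n_samples centerline samples per branch.
#' @param noise_px s.d. of Gaussian jitter added to the projected 2D points,
#'   in pixels.
#' @param frames optional list(n = c(m, p), period, phase_shift, amplitude)
#'   describing the two acquisitions' frame schedules: counts, cardiac
#'   period in frames, secondary-view phase shift in frames, and motion
#'   amplitude in mm.
#' @param seed RNG seed; all generated data are deterministic given the
#'   seed.
#' @return a list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(branches, parent = NA, poses, n_samples = 200,
                         noise_px = 0, frames = NULL, seed = 1) {
  structure(list(branches = branches, parent = parent, poses = poses,
                 n_samples = n_samples, noise_px = noise_px,
                 frames = frames, seed = seed),
            class = "phantom_spec")
}

# frames along a sampled curve: finite-difference tangents + rotation
# minimizing normals (exact enough for silhouette construction)
.sampled_frames <- function(P) {
  n <- nrow(P)
  Tm <- rbind(P[2, ] - P[1, ],
              (P[3:n, ] - P[1:(n - 2), ]),
              P[n, ] - P[n - 1, ])
  Tm <- Tm / sqrt(rowSums(Tm^2))
  Nm <- Bm <- matrix(0, n, 3)
  ref <- c(0, 0, 1)
  if (abs(sum(ref * Tm[1, ])) > 0.9) ref <- c(0, 1, 0)
  Nm[1, ] <- .normalize(ref - sum(ref * Tm[1, ]) * Tm[1, ])
  Bm[1, ] <- cross3(Tm[1, ], Nm[1, ])
  for (i in 2:n) {
    v1 <- P[i, ] - P[i - 1, ]
    c1 <- sum(v1 * v1)
    Nv <- if (c1 < 1e-300) Nm[i - 1, ] else {
      NL <- Nm[i - 1, ] - (2 / c1) * sum(v1 * Nm[i - 1, ]) * v1
      TL <- Tm[i - 1, ] - (2 / c1) * sum(v1 * Tm[i - 1, ]) * v1
      v2 <- Tm[i, ] - TL
      c2 <- sum(v2 * v2)
      if (c2 < 1e-300) NL else NL - (2 / c2) * sum(v2 * NL) * v2
    }
    Nm[i, ] <- .normalize(Nv - sum(Nv * Tm[i, ]) * Tm[i, ])
    Bm[i, ] <- cross3(Tm[i, ], Nm[i, ])
  }
  list(T = Tm, N = Nm, B = Bm)
}

# exact silhouette boundary points of a circular tube seen from focal point F:
# on each cross-section the surface normal is radial, so the grazing
# condition (P - F) . u(phi) = 0 with P = C + r u(phi) reads
# a cos(phi) + b sin(phi) = -r, a = (C-F).N, b = (C-F).B
.silhouette <- function(P, fr, r, F) {
  rel <- sweep(P, 2, F)
  a <- rowSums(rel * fr$N); b <- rowSums(rel * fr$B)
  Rh <- sqrt(a^2 + b^2)
  psi <- atan2(b, a)
  dphi <- acos(pmin(1, pmax(-1, -r / Rh)))
  mk <- function(phi) P + (cos(phi) * fr$N + sin(phi) * fr$B) * r
  list(mk(psi + dphi), mk(psi - dphi))
}

# ground-truth triangulated tube mesh of one branch
.tube_mesh <- function(P, fr, r, nv = 24) {
  n <- nrow(P)
  th <- 2 * pi * (seq_len(nv) - 1) / nv
  verts <- matrix(0, n * nv, 3)
  for (i in seq_len(n)) {
    ring <- matrix(P[i, ], nv, 3, byrow = TRUE) +
      r[i] * (outer(cos(th), fr$N[i, ]) + outer(sin(th), fr$B[i, ]))
    verts[((i - 1) * nv + 1):(i * nv), ] <- ring
  }
  idx <- function(i, j) (i - 1) * nv + ((j - 1) %% nv) + 1
  faces <- matrix(0L, (n - 1) * nv * 2, 3)
  rI <- 1
  for (i in seq_len(n - 1)) {
    for (j in seq_len(nv)) {
      a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      faces[rI, ] <- c(a, b, cc); faces[rI + 1, ] <- c(a, cc, d)
      rI <- rI + 2
    }
  }
  .orient_outward(list(vertices = verts, faces = faces))
}

#' Generate a synthetic XRA phantom
#'
#' Produces the ground-truth 3D tree (sampled centerlines, radii, frames and
#' triangulated tube surfaces) together with its exact perspective
#' projections under the specification's gantry poses: per-view 2D
#' centerline polylines and true silhouette borders (tangency rays, so
#' magnification effects are present), plus optional frame sequences of the
#' deforming bifurcation/end points for gating experiments.  Fully
#' deterministic given the specification's seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return object of class \code{xra_phantom}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr_seed(spec$seed, {
    nb <- length(spec$branches)
    s <- seq(0, 1, length.out = spec$n_samples)
    branches <- lapply(spec$branches, function(g) {
      P <- g$fn(s)
      fr <- .sampled_frames(P)
      r <- g$radius(s)
      list(points = P, radius = r, frames = fr,
           length = sum(sqrt(rowSums(diff(P)^2))))
    })
    meshes <- lapply(branches, function(b)
      .tube_mesh(b$points, b$frames, b$radius))

    views <- lapply(spec$poses, function(pose) {
      ctr <- lapply(branches, function(b) forward_project(b$points, pose))
      F <- .pose_frame(pose)$F
      bord <- lapply(branches, function(b) {
        sil <- .silhouette(b$points, b$frames, b$radius, F)
        list(forward_project(sil[[1]], pose), forward_project(sil[[2]], pose))
      })
      if (spec$noise_px > 0) {
        jit <- function(m, pose) m + matrix(rnorm(length(m), 0,
                     spec$noise_px * mean(pose$kappa)), nrow(m), 2)
        ctr <- lapply(ctr, jit, pose = pose)
        bord <- lapply(bord, function(bb) lapply(bb, jit, pose = pose))
      }
      list(pose = pose, centerlines = ctr, borders = bord)
    })

    # sample points for calibration/gating: branch end points plus
    # bifurcation points (branch junctions)
    ends <- do.call(rbind, lapply(branches, function(b)
      rbind(b$points[1, ], b$points[nrow(b$points), ])))
    samples3d <- unique(round(ends, 9))

    frames_out <- NULL
    if (!is.null(spec$frames)) {
      fs <- spec$frames
      np <- nrow(samples3d)
      dirs <- matrix(rnorm(np * 3), np, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      dirs2 <- matrix(rnorm(np * 3), np, 3)
      dirs2 <- dirs2 / sqrt(rowSums(dirs2^2))
      ph1 <- runif(np, 0, 2 * pi)
      ph2 <- runif(np, 0, 2 * pi)
      # two-harmonic per-point motion: like the cardiac cycle it is
      # periodic but time-asymmetric, so no two distinct phases produce
      # the same configuration of all points
      phase_points <- function(phase) {
        samples3d + fs$amplitude * (sin(2 * pi * phase + ph1) * dirs +
                                    0.4 * sin(4 * pi * phase + ph2) * dirs2)
      }
      offs <- c(0, fs$phase_shift)
      jit <- if (is.null(fs$jitter)) 0.2 else fs$jitter
      frames_out <- lapply(seq_along(spec$poses), function(i) {
        pose <- spec$poses[[i]]
        lapply(seq_len(fs$n[i]), function(k) {
          # sub-frame timing jitter: the two views come from different
          # heartbeats, so nominally corresponding frames never sample
          # exactly the same phase
          ph <- (k - 1 + offs[i] + rnorm(1, 0, jit)) / fs$period
          q <- forward_project(phase_points(ph), pose)
          if (spec$noise_px > 0)
            q <- q + matrix(rnorm(length(q), 0, spec$noise_px * mean(pose$kappa)),
                            nrow(q), 2)
          q
        })
      })
    }
    structure(list(spec = spec, branches = branches, meshes = meshes,
                   views = views, samples3d = samples3d,
                   frame_sequences = frames_out),
              class = "xra_phantom")
  })
}

#' @export
print.xra_phantom <- function(x, ...) {
  cat(sprintf("XRA phantom: %d branch(es), %d view(s), %d samples/branch\n",
              length(x$branches), length(x$views), x$spec$n_samples))
  invisible(x)
}

#' Rasterize one phantom view into an intensity image
#'
#' Renders the projected tube as a dark band (attenuating vessel) on a
#' bright background with a soft edge, for exercising the 2D segmentation
#' operators on known geometry.
#'
#' @param phantom an \code{xra_phantom}.
#' @param view view index.
#' @param dim image size in pixels c(width, height).
#' @param branch branch index or vector (default all).
#' @return matrix (rows = image rows) of intensities in [0, 1].
#' @export
render_view <- function(phantom, view, dim = c(200, 200), branch = NULL) {
  vw <- phantom$views[[view]]
  pose <- vw$pose
  if (is.null(branch)) branch <- seq_along(phantom$branches)
  img <- matrix(1, dim[2], dim[1])
  for (bi in branch) {
    c2 <- vw$centerlines[[bi]]
    b1 <- vw$borders[[bi]][[1]]; b2 <- vw$borders[[bi]][[2]]
    halfw_px <- sqrt(rowSums((b1 - b2)^2)) / 2 / mean(pose$kappa)
    px <- cbind(c2[, 1] / pose$kappa[1] + dim[1] / 2,
                c2[, 2] / pose$kappa[2] + dim[2] / 2)
    for (i in seq_len(nrow(px))) {
      w <- ceiling(halfw_px[i]) + 2
      c0 <- max(1, floor(px[i, 1] - w)); c1 <- min(dim[1], ceiling(px[i, 1] + w))
      r0 <- max(1, floor(px[i, 2] - w)); r1 <- min(dim[2], ceiling(px[i, 2] + w))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      dd <- sqrt(outer((rows - px[i, 2])^2, (cols - px[i, 1])^2, "+"))
      val <- 0.2 + 0.8 * pmin(1, pmax(0, (dd - halfw_px[i]) + 0.5))
      img[rows, cols] <- pmin(img[rows, cols], val)
    }
  }
  img
}

#' Assemble phantom branch generators into a meshable coronary tree
#'
#' Builds analytic \code{branch_centerline}/\code{branch_surface} pairs
#' (circular cross-sections at the generators' radii) from branch
#' generators and wraps them as a \code{\link{coronary_tree}}, ready for
#' \code{\link{trim_and_merge}}.  This is the ground-truth counterpart of
#' the imaging pipeline: no projection or reconstruction is involved.
#'
#' @param branches list of branch generators.
#' @param parent parent index vector (NA for the root).
#' @param q cross-section patches per branch.
#' @param w circular samples per patch.
#' @param n_curve centerline samples per branch for the spline fit.
#' @return a \code{coronary_tree}.
#' @export
phantom_tree <- function(branches, parent, q = 20, w = 16, n_curve = 40) {
  mk <- function(g) {
    s <- seq(0, 1, length.out = n_curve)
    pts <- g$fn(s)
    curve <- fit_bspline(pts, 4, min(n_curve, 12))
    frames <- frenet_frames(curve, seq(0, 1, length.out = 100), method = "rmf")
    rc <- structure(list(curve = curve, samples = pts, frames = frames,
                         match = NULL), class = "branch_centerline")
    ts <- seq(0, 1, length.out = q)
    fr <- frenet_frames(curve, ts, method = "rmf")
    rads <- g$radius(ts)
    patches <- lapply(seq_along(ts), function(i) {
      structure(list(center = as.numeric(eval_bspline(curve, ts[i])),
                     t = ts[i],
                     frame = list(T = fr$T[i, ], N = fr$N[i, ], B = fr$B[i, ]),
                     points2d = NULL, complete = TRUE,
                     ill_conditioned = FALSE,
                     fit = structure(list(mode = "circle", center = c(0, 0),
                                          radius = rads[i]),
                                     class = "cross_section_fit")),
                class = "cross_section_patch")
    })
    list(centerline = rc, surface = assemble_surface(patches, w = w))
  }
  coronary_tree(lapply(branches, mk), parent)
}
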