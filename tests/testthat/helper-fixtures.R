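# shared fixtures, all generated in code

ap_pose <- function() gantry_pose(0, 0)

# points of a straight segment
line_pts <- function(a, b, n = 40) {
  s <- seq(0, 1, length.out = n)
  outer(1 - s, a) + outer(s, b)
}

# analytic tube branch -> branch_centerline + branch_surface (no imaging)
make_tube_branch <- function(pts, radius, q = 20, w = 16) {
  n <- nrow(pts)
  curve <- fit_bspline(pts, 4, min(n, 12))
  frames <- frenet_frames(curve, seq(0, 1, length.out = 100), method = "rmf")
  rc <- structure(list(curve = curve, samples = pts, frames = frames,
                       match = NULL), class = "branch_centerline")
  ts <- seq(0, 1, length.out = q)
  fr <- frenet_frames(curve, ts, method = "rmf")
  patches <- lapply(seq_along(ts), function(i) {
    structure(list(center = as.numeric(eval_bspline(curve, ts[i])),
                   t = ts[i],
                   frame = list(T = fr$T[i, ], N = fr$N[i, ], B = fr$B[i, ]),
                   points2d = NULL, complete = TRUE, ill_conditioned = FALSE,
                   fit = structure(list(mode = "circle", center = c(0, 0),
                                        radius = radius),
                                   class = "cross_section_fit")),
              class = "cross_section_patch")
  })
  list(centerline = rc, surface = assemble_surface(patches, w = w))
}

# symmetric Y tree of straight tubes (children at +-half_angle from parent)
make_y_tree <- function(half_angle = 30, r_parent = 1.5, r_child = 1.25,
                        len = 20) {
  a <- half_angle * pi / 180
  p0 <- make_tube_branch(line_pts(c(0, 0, 0), c(0, len, 0)), r_parent)
  c1 <- make_tube_branch(line_pts(c(0, len, 0),
                                  c(0, len, 0) + len * c(-sin(a), cos(a), 0)),
                         r_child)
  c2 <- make_tube_branch(line_pts(c(0, len, 0),
                                  c(0, len, 0) + len * c(sin(a), cos(a), 0)),
                         r_child)
  coronary_tree(list(p0, c1, c2), c(NA, 1, 1))
}

# latitude-longitude sphere triangle mesh
make_sphere_mesh <- function(radius, n_lat = 18, n_lon = 36,
                             center = c(0, 0, 0)) {
  th <- seq(0, pi, length.out = n_lat)
  phi <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  verts <- NULL
  for (t in th)
    verts <- rbind(verts, cbind(radius * sin(t) * cos(phi),
                                radius * sin(t) * sin(phi),
                                radius * cos(t)))
  verts <- sweep(verts, 2, center, "+")
  idx <- function(i, j) (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  faces <- NULL
  for (i in seq_len(n_lat - 1)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      faces <- rbind(faces, c(a, cc, b), c(a, d, cc))
    }
  }
  # orient outward
  A <- verts[faces[, 1], ]; B <- verts[faces[, 2], ]; C <- verts[faces[, 3], ]
  nrm <- cbind((B[,2]-A[,2])*(C[,3]-A[,3]) - (B[,3]-A[,3])*(C[,2]-A[,2]),
               (B[,3]-A[,3])*(C[,1]-A[,1]) - (B[,1]-A[,1])*(C[,3]-A[,3]),
               (B[,1]-A[,1])*(C[,2]-A[,2]) - (B[,2]-A[,2])*(C[,1]-A[,1]))
  out <- rowSums(nrm * (sweep((A + B + C) / 3, 2, center))) < 0
  faces[out, ] <- faces[out, c(1, 3, 2)]
  list(vertices = verts, faces = faces)
}

# two-view cylinder phantom used across modules
cylinder_phantom <- function(alpha2 = 60, radius = 1.5, seed = 3,
                             n_samples = 200) {
  pose1 <- gantry_pose(0, 0)
  pose2 <- gantry_pose(alpha2, 0)
  br <- branch_line(c(-5, -20, 2), c(0.15, 1, 0.1), 40, radius)
  spec <- phantom_spec(list(br), NA, list(pose1, pose2),
                       n_samples = n_samples, seed = seed)
  generate_phantom(spec)
}

# compact GA settings for unit tests (full defaults are exercised in the
# acceptance suite)
fast_ga <- function(seed = 1, ...) {
  ga_config(population = 40, generations = 40, seed = seed,
            polish = TRUE, polish_rounds = 2, profile = FALSE, ...)
}

unit_vec <- function(v) v / sqrt(sum(v^2))
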