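# ---------------------------------------------------------------------------
# B-spline basis (Cox-de Boor), curve fitting, evaluation and moving frames.
# "Order" k follows the classic convention: k = degree + 1 (k = 4 is cubic).
# ---------------------------------------------------------------------------

# Cox-de Boor basis matrix: length(t) x (length(knots) - k), with the 0/0 = 0
# convention and the clamped right end evaluated by closure from the left.
bspline_basis <- function(t, knots, k, deriv = 0) {
  n <- length(knots) - k
  stopifnot(n >= k || deriv > 0, all(diff(knots) >= 0))
  tmax <- knots[n + 1]               # end of the valid domain for clamped knots
  t_eval <- pmin(t, tmax - 1e-12 * max(1, abs(tmax)))
  if (deriv == 0) {
    B <- .cdb(t_eval, knots, k)
    # exact closure at the right end of a clamped vector
    at_end <- t >= tmax
    if (any(at_end) && knots[n + 1] == knots[n + k]) {
      B[at_end, ] <- 0
      B[at_end, n] <- 1
    }
    return(B)
  }
  # derivative: d/dt N_{i,k} = (k-1) * (N_{i,k-1}/den1 - N_{i+1,k-1}/den2)
  Bd <- bspline_basis(t_eval, knots, k - 1, deriv - 1)
  out <- matrix(0, length(t), n)
  for (i in seq_len(n)) {
    d1 <- knots[i + k - 1] - knots[i]
    d2 <- knots[i + k] - knots[i + 1]
    v <- 0
    if (d1 > 0) v <- v + Bd[, i] / d1
    if (d2 > 0) v <- v - Bd[, i + 1] / d2
    out[, i] <- (k - 1) * v
  }
  out
}

.cdb <- function(t, knots, k) {
  nb <- length(knots) - 1
  B <- matrix(0, length(t), nb)
  for (i in seq_len(nb)) B[, i] <- (t >= knots[i] & t < knots[i + 1]) * 1
  if (k == 1) return(B[, seq_len(length(knots) - 1), drop = FALSE])
  for (ord in 2:k) {
    nn <- length(knots) - ord
    Bn <- matrix(0, length(t), nn)
    for (i in seq_len(nn)) {
      d1 <- knots[i + ord - 1] - knots[i]
      d2 <- knots[i + ord] - knots[i + 1]
      v <- 0
      if (d1 > 0) v <- v + (t - knots[i]) / d1 * B[, i]
      if (d2 > 0) v <- v + (knots[i + ord] - t) / d2 * B[, i + 1]
      Bn[, i] <- v
    }
    B <- Bn
  }
  B
}

# chord-length parameter assignment, in [0, 1]
chord_params <- function(points) {
  d <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(d))
  if (s[length(s)] == 0) stop("all points coincide")
  s / s[length(s)]
}

# clamped knot vector by parameter averaging (interpolation) or uniform
# quantiles of the parameters (least squares with n_ctrl < n)
.clamped_knots <- function(tbar, n_ctrl, k) {
  n <- length(tbar)
  if (n_ctrl == n) {
    interior <- if (n_ctrl > k)
      vapply(seq_len(n_ctrl - k), function(j) mean(tbar[(j + 1):(j + k - 1)]),
             numeric(1))
    else numeric(0)
  } else {
    d <- n / (n_ctrl - k + 1)
    interior <- vapply(seq_len(n_ctrl - k), function(j) {
      i <- floor(j * d); a <- j * d - i
      (1 - a) * tbar[i] + a * tbar[i + 1]
    }, numeric(1))
  }
  c(rep(0, k), interior, rep(1, k))
}

#' Fit a nonuniform B-spline curve to ordered 3D points
#'
#' Chord-length parameter assignment with a clamped knot vector; interpolating
#' when \code{n_ctrl} equals the number of points, least-squares smoothing
#' otherwise (with the two end control points constrained to the end data
#' points).  Consecutive duplicate points are removed with a warning.
#'
#' @param points n x 3 matrix of ordered points (n >= k).
#' @param k spline order (degree + 1); default 4 (cubic).
#' @param n_ctrl number of control points; default
#'   \code{min(n, max(6, round(n/3)))}.
#' @return object of class \code{bspline_curve} with fields
#'   \code{control}, \code{knots}, \code{k} and the data parameters
#'   \code{tbar}.
#' @export
fit_bspline <- function(points, k = 4, n_ctrl = NULL) {
  points <- as.matrix(points)
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  if (any(dup)) {
    warning(sprintf("removed %d coincident consecutive points", sum(dup)))
    points <- points[!dup, , drop = FALSE]
  }
  n <- nrow(points)
  if (is.null(n_ctrl)) n_ctrl <- min(n, max(6, round(n / 3)))
  n_ctrl <- max(k, min(n, n_ctrl))
  stopifnot(n >= k)
  tbar <- chord_params(points)
  knots <- .clamped_knots(tbar, n_ctrl, k)
  B <- bspline_basis(tbar, knots, k)
  if (n_ctrl == n) {
    ctrl <- solve(B, points)
  } else {
    # clamp the curve ends to the end data points
    fixed <- rbind(points[1, ], points[n, ])
    Bmid <- B[, -c(1, n_ctrl), drop = FALSE]
    rhs <- points - B[, c(1, n_ctrl), drop = FALSE] %*% fixed
    mid <- qr.solve(Bmid, rhs)
    ctrl <- rbind(fixed[1, ], mid, fixed[2, ])
  }
  structure(list(control = ctrl, knots = knots, k = k, tbar = tbar),
            class = "bspline_curve")
}

#' Evaluate a B-spline curve
#'
#' @param curve a \code{bspline_curve}.
#' @param t parameter values in [0, 1].
#' @param deriv derivative order (0 = position).
#' @return length(t) x 3 matrix.
#' @export
eval_bspline <- function(curve, t, deriv = 0) {
  B <- bspline_basis(t, curve$knots, curve$k, deriv)
  B %*% curve$control
}

#' @export
print.bspline_curve <- function(x, ...) {
  cat(sprintf("B-spline curve: order %d, %d control points, length %.3f mm\n",
              x$k, nrow(x$control), bspline_length(x)))
  invisible(x)
}

#' Arc length of a B-spline curve
#'
#' Composite Gauss-Legendre quadrature of |C'(t)| over [0, 1].
#'
#' @param curve a \code{bspline_curve}.
#' @param n_seg number of quadrature segments.
#' @return curve length in the curve's units (mm).
#' @export
bspline_length <- function(curve, n_seg = 200) {
  # 3-point Gauss-Legendre per segment
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2
  gw <- c(5 / 9, 8 / 9, 5 / 9) / 2
  edges <- seq(0, 1, length.out = n_seg + 1)
  mid <- (edges[-1] + edges[-(n_seg + 1)]) / 2
  h <- diff(edges)
  tq <- as.numeric(outer(gx, h) + rep(mid, each = 3))
  wq <- as.numeric(outer(gw, h))
  sp <- sqrt(rowSums(eval_bspline(curve, tq, 1)^2))
  sum(sp * wq)
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

#' Moving orthonormal frames along a curve
#'
#' Computes right-handed tangent/normal/binormal triads at the requested
#' parameters.  With \code{method = "frenet"} the normal follows the
#' curvature vector (Frenet-Serret) wherever the curvature exceeds
#' \code{curv_tol}; straight runs are bridged by rotation-minimizing
#' (parallel-transport) continuation so the frame is defined everywhere and
#' never flips.  With \code{method = "rmf"} the whole frame sequence is
#' rotation-minimizing (double-reflection), optionally seeded with
#' \code{seed_normal}.
#'
#' @param curve a \code{bspline_curve}.
#' @param ts increasing parameter values in [0, 1].
#' @param method "frenet" or "rmf".
#' @param curv_tol curvature threshold (1/mm) below which Frenet is
#'   undefined and parallel transport is used.
#' @param seed_normal optional 3-vector seeding the first normal (projected
#'   onto the first normal plane).
#' @return list with matrices \code{T}, \code{N}, \code{B} (rows = frames)
#'   and the parameter vector \code{ts}.
#' @export
frenet_frames <- function(curve, ts, method = c("frenet", "rmf"),
                          curv_tol = 1e-6, seed_normal = NULL) {
  method <- match.arg(method)
  C0 <- eval_bspline(curve, ts, 0)
  C1 <- eval_bspline(curve, ts, 1)
  C2 <- eval_bspline(curve, ts, 2)
  n <- length(ts)
  Tm <- Nm <- Bm <- matrix(0, n, 3)
  sp <- sqrt(rowSums(C1^2))
  if (any(sp == 0)) stop("zero-length tangent: degenerate parameterization")
  Tm <- C1 / sp
  # curvature vector kappa = (C'' - (C''.T)T) / |C'|^2 ; |kappa| in 1/mm
  proj <- rowSums(C2 * Tm)
  Kv <- (C2 - proj * Tm) / sp^2
  kap <- sqrt(rowSums(Kv^2))

  seed_frame <- function(Tv) {
    ref <- if (!is.null(seed_normal)) seed_normal else {
      a <- c(0, 0, 1)
      if (abs(sum(a * Tv)) > 0.9) a <- c(0, 1, 0)
      a
    }
    Nv <- ref - sum(ref * Tv) * Tv
    if (sqrt(sum(Nv^2)) < 1e-12) stop("seed normal parallel to the tangent")
    Nv <- .normalize(Nv)
    list(N = Nv, B = .normalize(cross3(Tv, Nv)))
  }

  # double-reflection rotation-minimizing transport of N from frame i-1 to i
  transport <- function(Nprev, Pprev, Tprev, Pcur, Tcur) {
    v1 <- Pcur - Pprev
    c1 <- sum(v1 * v1)
    if (c1 < 1e-300) return(Nprev)
    NL <- Nprev - (2 / c1) * sum(v1 * Nprev) * v1
    TL <- Tprev - (2 / c1) * sum(v1 * Tprev) * v1
    v2 <- Tcur - TL
    c2 <- sum(v2 * v2)
    if (c2 < 1e-300) return(NL)
    NL - (2 / c2) * sum(v2 * NL) * v2
  }

  use_frenet <- method == "frenet" & kap > curv_tol
  for (i in seq_len(n)) {
    if (use_frenet[i]) {
      Nv <- Kv[i, ] / kap[i]
    } else if (i == 1) {
      Nv <- seed_frame(Tm[1, ])$N
    } else {
      Nv <- transport(Nm[i - 1, ], C0[i - 1, ], Tm[i - 1, ], C0[i, ], Tm[i, ])
      Nv <- .normalize(Nv - sum(Nv * Tm[i, ]) * Tm[i, ])
    }
    if (method == "rmf" && i > 1) {
      Nv <- transport(Nm[i - 1, ], C0[i - 1, ], Tm[i - 1, ], C0[i, ], Tm[i, ])
      Nv <- .normalize(Nv - sum(Nv * Tm[i, ]) * Tm[i, ])
    }
    if (i == 1 && method == "rmf") Nv <- seed_frame(Tm[1, ])$N
    Nm[i, ] <- Nv
    Bm[i, ] <- .normalize(cross3(Tm[i, ], Nv))
  }
  # the first Frenet frame of a straight lead-in must look ahead: re-transport
  if (method == "frenet" && !use_frenet[1] && any(use_frenet)) {
    j <- which(use_frenet)[1]
    for (i in seq(j - 1, 1)) {
      Nv <- transport(Nm[i + 1, ], C0[i + 1, ], Tm[i + 1, ], C0[i, ], Tm[i, ])
      Nm[i, ] <- .normalize(Nv - sum(Nv * Tm[i, ]) * Tm[i, ])
      Bm[i, ] <- .normalize(cross3(Tm[i, ], Nm[i, ]))
    }
  }
  list(T = Tm, N = Nm, B = Bm, ts = ts, curvature = kap)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---------------------------------------------------------------------------
# periodic (closed) uniform B-spline in the circular direction
# ---------------------------------------------------------------------------

# basis matrix for a closed uniform B-spline with w control points, order l,
# evaluated at v in [0, 1); column j multiplies control point j (wrapped).
periodic_basis <- function(v, w, l) {
  v <- v %% 1
  knots <- seq(-(l - 1), w + l - 1) / w      # uniform, extended
  Bx <- .cdb(v, knots, l)                    # columns: w + l - 1 wrapped bases
  out <- matrix(0, length(v), w)
  for (j in seq_len(ncol(Bx))) {
    cj <- ((j - l) %% w) + 1                 # control index of extended basis j
    out[, cj] <- out[, cj] + Bx[, j]
  }
  out
}

# closed-curve interpolation: control ring c (w x d) through points y at
# v_j = (j-1)/w
periodic_interp <- function(y) {
  w <- nrow(y)
  A <- periodic_basis((seq_len(w) - 1) / w, w, 4)
  solve(A, y)
}
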