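# ---------------------------------------------------------------------------
# Small 2D polyline helpers shared by segmentation, matching and the
# surface builder.  A polyline is an n x 2 matrix of ordered points (mm);
# its parameterization is normalized arc length in [0, 1].
# ---------------------------------------------------------------------------

#' Normalized arc-length parameters of a polyline
#' @param pts n x 2 (or n x 3) matrix of ordered points.
#' @return numeric vector in [0, 1], strictly increasing.
#' @export
polyline_params <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  s / s[length(s)]
}

#' Resample a polyline uniformly by arc length
#' @param pts n x 2 (or n x 3) matrix.
#' @param n number of output points.
#' @return n x ncol(pts) matrix.
#' @export
resample_polyline <- function(pts, n) {
  pts <- as.matrix(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  s <- polyline_params(pts)
  so <- seq(0, 1, length.out = n)
  apply(pts, 2, function(col) approx(s, col, xout = so)$y)
}

# position on the polyline at normalized arc parameter s
polyline_point <- function(pts, s) {
  sp <- polyline_params(pts)
  vapply(seq_len(ncol(pts)),
         function(j) approx(sp, pts[, j], xout = s)$y, numeric(length(s)))
}

# unit tangent at parameter s by central differencing of the arc mapping
polyline_tangent <- function(pts, s, h = 5e-3) {
  a <- polyline_point(pts, pmax(s - h, 0))
  b <- polyline_point(pts, pmin(s + h, 1))
  d <- matrix(b - a, ncol = ncol(pts))
  d / sqrt(rowSums(d^2))
}

# intersect the (infinite) line p + t*dir with a polyline; returns the
# intersection closest to p within max_dist, or NULL
polyline_line_intersect <- function(pts, p, dir, max_dist = Inf) {
  nrm <- c(-dir[2], dir[1])                    # normal of the cutting line
  f <- as.numeric((sweep(pts, 2, p)) %*% nrm)  # signed side of each vertex
  idx <- which(f[-length(f)] * f[-1] <= 0)
  if (length(idx) == 0) return(NULL)
  best <- NULL; bd <- max_dist
  for (i in idx) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    denom <- f[i] - f[i + 1]
    u <- if (denom == 0) 0 else f[i] / denom
    x <- a + u * (b - a)
    d <- sqrt(sum((x - p)^2))
    if (d < bd) { bd <- d; best <- x }
  }
  best
}
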