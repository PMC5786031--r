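# ---------------------------------------------------------------------------
# Validation metrics: signed surface deviation, Hausdorff distance and
# centerline-length agreement statistics.
# ---------------------------------------------------------------------------

#' Signed surface deviation between two triangle meshes
#'
#' For every vertex of the test mesh, the distance to the closest point of
#' the reference surface, signed by the reference's outward normal at that
#' point: positive where the test surface lies outside the reference
#' (overestimated lumen), negative inside (e.g. an omitted narrowing).  The
#' meshes must already be aligned.
#'
#' @param test,reference lists with \code{vertices} (n x 3) and
#'   \code{faces} (m x 3, 1-based, outward-oriented reference).
#' @return object of class \code{deviation_report}: per-vertex
#'   \code{deviation}, summary statistics (mean and max of the positive and
#'   negative sides, overall sd) and symmetric Hausdorff statistics.
#' @export
signed_deviation <- function(test, reference) {
  stopifnot(nrow(test$vertices) > 0, nrow(reference$vertices) > 0)
  res <- cx_point_mesh(test$vertices, reference$vertices, reference$faces)
  dev <- res$dist * res$sign
  pos <- dev[dev > 0]; neg <- dev[dev < 0]
  hd <- hausdorff_distance(test, reference)
  structure(list(
    deviation = dev,
    summary = list(
      mean_pos = if (length(pos)) mean(pos) else 0,
      mean_neg = if (length(neg)) mean(neg) else 0,
      max_pos = if (length(pos)) max(pos) else 0,
      max_neg = if (length(neg)) min(neg) else 0,
      mean_abs = mean(abs(dev)),
      sd = sd(dev)),
    hausdorff = hd,
    n_degenerate = res$n_degenerate),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Surface deviation: mean %+0.4f / %+0.4f mm, max %+0.4f / %+0.4f mm, sd %.4f mm\n",
              s$mean_pos, s$mean_neg, s$max_pos, s$max_neg, s$sd))
  cat(sprintf("Hausdorff: max %.4f mm, mean %.4f mm, sd %.4f mm\n",
              x$hausdorff$max, x$hausdorff$mean, x$hausdorff$sd))
  invisible(x)
}

#' @export
plot.deviation_report <- function(x, ...) {
  graphics::hist(x$deviation, breaks = 40, main = "Signed surface deviation",
                 xlab = "deviation (mm)", ...)
  invisible(x)
}

#' Symmetric Hausdorff distance between two triangle meshes
#'
#' Vertex-to-surface distances in both directions; the maximum of the two
#' directed maxima, plus the mean and standard deviation of the pooled
#' directed distances.
#'
#' @inheritParams signed_deviation
#' @return list with \code{max}, \code{mean}, \code{sd} (mm).
#' @export
hausdorff_distance <- function(test, reference) {
  d1 <- cx_point_mesh(test$vertices, reference$vertices, reference$faces)$dist
  d2 <- cx_point_mesh(reference$vertices, test$vertices, test$faces)$dist
  list(max = max(max(d1), max(d2)), mean = mean(c(d1, d2)), sd = sd(c(d1, d2)))
}

#' Centerline-length agreement statistics
#'
#' Pearson correlation (as r squared), mean difference, mean absolute
#' difference and the standard deviation of the differences between
#' reconstructed and ground-truth branch lengths, plus the Bland-Altman
#' pairs.
#'
#' @param recon,truth equal-length numeric vectors (n >= 3) of branch
#'   lengths, mm.
#' @return list with \code{r_squared}, \code{mean_diff},
#'   \code{mean_abs_diff}, \code{sd_diff} and \code{bland_altman}
#'   (two-column matrix of per-case means and differences).
#' @export
length_agreement <- function(recon, truth) {
  stopifnot(length(recon) == length(truth), length(recon) >= 3)
  d <- recon - truth
  list(r_squared = cor(recon, truth)^2,
       mean_diff = mean(d),
       mean_abs_diff = mean(abs(d)),
       sd_diff = sd(d),
       bland_altman = cbind(mean = (recon + truth) / 2, diff = d))
}

#' Rigid ICP alignment of a mesh to a reference surface
#'
#' Iterative closest point with a Kabsch rigid update: each iteration pairs
#' every vertex of the moving mesh with its closest point on the reference
#' surface and applies the least-squares rotation/translation.  Intended
#' for externally supplied meshes; phantom-based validation needs no
#' alignment because the pose is known.
#'
#' @param moving,reference lists with \code{vertices}/\code{faces}.
#' @param iterations maximum ICP iterations.
#' @param tol stop when the mean pairing distance improves less than this.
#' @return the moving mesh with transformed vertices; attributes
#'   \code{rotation}, \code{translation}, \code{rmse}.
#' @export
align_icp <- function(moving, reference, iterations = 30, tol = 1e-6) {
  V <- moving$vertices
  Rtot <- diag(3); ttot <- c(0, 0, 0)
  last <- Inf
  for (it in seq_len(iterations)) {
    res <- cx_point_mesh(V, reference$vertices, reference$faces)
    Q <- res$closest
    mV <- colMeans(V); mQ <- colMeans(Q)
    H <- crossprod(sweep(V, 2, mV), sweep(Q, 2, mQ))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    tvec <- mQ - as.numeric(R %*% mV)
    V <- sweep(V %*% t(R), 2, tvec, "+")
    Rtot <- R %*% Rtot; ttot <- as.numeric(R %*% ttot) + tvec
    now <- mean(res$dist)
    if (abs(last - now) < tol) break
    last <- now
  }
  out <- moving
  out$vertices <- V
  attr(out, "rotation") <- Rtot
  attr(out, "translation") <- ttot
  attr(out, "rmse") <- sqrt(mean(cx_point_mesh(V, reference$vertices,
                                               reference$faces)$dist^2))
  out
}

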