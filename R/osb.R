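#' Skip penalty of a dissimilarity matrix
#'
#' The penalty charged per unit of skipped sequence distance during optimal
#' subsequence bijection: the minimum over rows of the row-minima plus the
#' (population) standard deviation of the row-minima.
#'
#' @param delta m x p matrix of nonnegative finite dissimilarities.
#' @return a single nonnegative number.
#' @export
skip_penalty <- function(delta) {
  delta <- as.matrix(delta)
  stopifnot(nrow(delta) >= 1, ncol(delta) >= 1, all(is.finite(delta)))
  rm <- apply(delta, 1, min)
  pop_sd <- sqrt(mean((rm - mean(rm))^2))
  min(rm) + pop_sd
}

#' Optimal subsequence bijection
#'
#' Finds the minimum-cost strictly monotone one-to-one correspondence
#' between two sequences given their dissimilarity matrix, allowing outlier
#' elements of either sequence to be skipped at a penalty.  Jumping from
#' pair (q, w) to pair (k, l) with q < k and w < l costs
#' \code{sqrt((k-q-1)^2 + (l-w-1)^2) * xi + delta[k, l]}; virtual source
#' and sink elements precede and follow both sequences and carry no node
#' cost, so leading/trailing elements are skipped under the same formula.
#' Cost ties are broken toward paths with more pairs.
#'
#' @param delta m x p nonnegative dissimilarity matrix.
#' @param xi nonnegative skip penalty (see \code{\link{skip_penalty}}).
#' @return object of class \code{correspondence_path}: a two-column matrix
#'   \code{pairs} of 1-based indices, strictly increasing in both columns,
#'   and the \code{cost} of the optimal path.
#' @export
osb_match <- function(delta, xi) {
  delta <- as.matrix(delta)
  stopifnot(xi >= 0)
  if (nrow(delta) == 0 || ncol(delta) == 0)
    return(structure(list(pairs = matrix(integer(0), 0, 2), cost = 0),
                     class = "correspondence_path"))
  stopifnot(all(is.finite(delta)), all(delta >= 0))
  res <- cx_osb_dp(delta, xi)
  structure(list(pairs = res$pairs, cost = res$cost),
            class = "correspondence_path")
}

#' @export
print.correspondence_path <- function(x, ...) {
  cat(sprintf("Correspondence path: %d pairs, cost %.6g\n",
              nrow(x$pairs), x$cost))
  invisible(x)
}

#' Exhaustive-search reference for optimal subsequence bijection
#'
#' Enumerates every nonempty strictly monotone one-to-one correspondence
#' between the two sequences and returns the minimum-cost one under the same
#' cost model as \code{\link{osb_match}}.  Exponential; intended as an
#' independent check on small instances (m, p <= ~8).
#'
#' @inheritParams osb_match
#' @return list with \code{pairs} and \code{cost}.
#' @export
osb_enumerate <- function(delta, xi) {
  delta <- as.matrix(delta)
  m <- nrow(delta); p <- ncol(delta)
  best <- list(cost = Inf, pairs = NULL)
  path_cost <- function(pairs) {
    k <- pairs[, 1]; l <- pairs[, 2]
    cost <- sqrt((k[1] - 1)^2 + (l[1] - 1)^2) * xi
    cost <- cost + sum(delta[cbind(k, l)])
    if (length(k) > 1) {
      dk <- diff(k) - 1; dl <- diff(l) - 1
      cost <- cost + sum(sqrt(dk^2 + dl^2)) * xi
    }
    n <- length(k)
    cost + xi * sqrt((m - k[n])^2 + (p - l[n])^2)
  }
  recurse <- function(pairs, qmin, wmin) {
    for (k in qmin:m) {
      if (k > m) break
      for (l in wmin:p) {
        if (l > p) break
        np <- rbind(pairs, c(k, l))
        cc <- path_cost(np)
        if (cc < best$cost ||
            (cc == best$cost && nrow(np) > nrow(best$pairs)))
          best <<- list(cost = cc, pairs = np)
        if (k < m && l < p) recurse(np, k + 1, l + 1)
      }
    }
  }
  recurse(matrix(integer(0), 0, 2), 1, 1)
  best
}

#' Dynamic time warping baseline
#'
#' Classic DTW alignment (many-to-many, step set down/right/diagonal) of two
#' sequences given their dissimilarity matrix; the comparison baseline for
#' optimal subsequence bijection.
#'
#' @param delta m x p nonnegative dissimilarity matrix.
#' @return list with \code{pairs} (two-column matrix of non-decreasing index
#'   pairs covering both sequences) and \code{cost}.
#' @export
dtw_match <- function(delta) {
  delta <- as.matrix(delta)
  m <- nrow(delta); p <- ncol(delta)
  if (m == 0 || p == 0) return(list(pairs = matrix(integer(0), 0, 2), cost = 0))
  D <- matrix(Inf, m + 1, p + 1)
  D[1, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(p)) {
      D[i + 1, j + 1] <- delta[i, j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrack
  i <- m; j <- p
  path <- list(c(m, p))
  while (i > 1 || j > 1) {
    opts <- c(if (i > 1 && j > 1) D[i - 1 + 1, j - 1 + 1] else Inf,
              if (i > 1) D[i - 1 + 1, j + 1] else Inf,
              if (j > 1) D[i + 1, j - 1 + 1] else Inf)
    step <- which.min(opts)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  pairs <- do.call(rbind, rev(path))
  list(pairs = pairs, cost = D[m + 1, p + 1])
}

#' Temporal gating of two XRA frame sequences
#'
#' Pairs frames of the primary and secondary acquisitions so that both show
#' the same cardiac phase, by optimal subsequence bijection.  The
#' dissimilarity of frame k (view 1) with frame l (view 2) is the two-view
#' reprojection mean square error of the sampled points of those frames
#' under the calibrated geometry; the skip penalty is derived from the
#' dissimilarity matrix itself.
#'
#' @param seq1,seq2 lists of n x 2 matrices: per-frame sampled detector
#'   points (mm) in the primary / secondary view.  Frames with missing
#'   points (NA or NULL) are excluded and reported.
#' @param calib an \code{xra_calibration}.
#' @return a \code{correspondence_path} whose pairs refer to the original
#'   frame indices; attributes \code{delta} (the dissimilarity matrix),
#'   \code{xi} and \code{excluded} (list of dropped frame indices per view).
#' @export
gate_frames <- function(seq1, seq2, calib) {
  ok1 <- vapply(seq1, function(q) !is.null(q) && all(is.finite(q)), logical(1))
  ok2 <- vapply(seq2, function(q) !is.null(q) && all(is.finite(q)), logical(1))
  idx1 <- which(ok1); idx2 <- which(ok2)
  m <- length(idx1); p <- length(idx2)
  if (m == 0 || p == 0) stop("no usable frames to gate")
  delta <- matrix(0, m, p)
  for (a in seq_len(m)) {
    for (b in seq_len(p)) {
      delta[a, b] <- reprojection_mse(calib$params, seq1[[idx1[a]]],
                                      seq2[[idx2[b]]],
                                      list(calib$pose1, calib$pose2))
    }
  }
  xi <- skip_penalty(delta)
  path <- osb_match(delta, xi)
  path$pairs <- cbind(idx1[path$pairs[, 1]], idx2[path$pairs[, 2]])
  attr(path, "delta") <- delta
  attr(path, "xi") <- xi
  attr(path, "excluded") <- list(primary = which(!ok1), secondary = which(!ok2))
  path
}
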