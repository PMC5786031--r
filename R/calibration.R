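#' Two-view reprojection mean square error
#'
#' The calibration objective: each 2D correspondence pair is triangulated
#' under the candidate geometry, the 3D point is ray-traced back onto both
#' detectors, and the squared 2D residuals of both views are summed and
#' divided by the number of point pairs (mm^2).
#'
#' @param params numeric length-11 vector
#'   \code{(alpha2, beta2, dtheta[3], dO[3], di[3])} describing the secondary
#'   view; the primary view is the ideal reference.
#' @param q1,q2 n x 2 matrices of detector mm coordinates (primary,
#'   secondary view); n >= 1.
#' @param base list of two \code{\link{gantry_pose}} objects giving distances
#'   and pixel spacing; the secondary pose's angles/misalignments are
#'   replaced by \code{params}.
#' @return the mean square reprojection error in mm^2.
#' @export
reprojection_mse <- function(params, q1, q2, base) {
  stopifnot(length(params) == 11)
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  n <- nrow(q1)
  stopifnot(nrow(q2) == n, n >= 1)
  pose1 <- base[[1]]
  pose2 <- .apply_params(base[[2]], params)
  tri <- .triangulate_views(q1, q2, pose1, pose2)
  r1 <- forward_project(tri$points, pose1) - q1
  r2 <- forward_project(tri$points, pose2) - q2
  (sum(r1^2) + sum(r2^2)) / n
}

.apply_params <- function(pose, params) {
  pose$alpha <- params[1]; pose$beta <- params[2]
  pose$dtheta <- params[3:5]; pose$dO <- params[6:8]; pose$di <- params[9:11]
  pose
}

.params_of_pose <- function(pose) {
  c(pose$alpha, pose$beta, pose$dtheta, pose$dO, pose$di)
}

#' Genetic-algorithm configuration for gantry calibration
#'
#' @param population,generations GA size; defaults 80 x 150.
#' @param tournament tournament selection size.
#' @param p_crossover SBX crossover probability per pair.
#' @param eta_crossover SBX distribution index.
#' @param p_mutation per-gene Gaussian mutation probability.
#' @param sigma0,sigma_final initial/final mutation s.d. as fractions of the
#'   search-box width (geometric decay across generations).
#' @param elitism number of elite individuals copied unchanged.
#' @param seed RNG seed for a deterministic run.
#' @param bound_angle,bound_dtheta,bound_trans half-widths of the search box:
#'   degrees around the DICOM angles, degrees of detector rotation, and mm of
#'   detector/isocenter translation.
#' @param gauge_lambda weight of the gauge-fixing prior.  The 11-parameter
#'   model is over-parameterized: a change of the positioner angles can be
#'   compensated exactly by the detector/isocenter translation terms, so the
#'   reprojection error alone leaves a null space.  The fitness therefore
#'   adds \code{gauge_lambda * ||(x - x0)/gauge_scale||^2}, which selects
#'   the reprojection-equivalent solution closest to the DICOM header
#'   values without measurably biasing the identifiable directions.
#' @param gauge_scale per-parameter prior scales: the header positioner
#'   angles are read out to a degree or two, while gantry sag can translate
#'   the detector/isocenter by centimetres, so the default is
#'   c(2, 2 deg; 5, 5, 5 deg; 20 mm x 6).
#' @param polish if \code{TRUE} (default), refine the GA optimum with
#'   alternating quasi-Newton/simplex rounds on the same fitness; the GA
#'   cannot slide far along the curved gauge manifold on its own.
#' @param polish_rounds refinement rounds.
#' @param profile if \code{TRUE} (default), finish with a profile stage:
#'   an outer simplex search over the two positioner angles with the nine
#'   misalignment terms re-optimised (quasi-Newton, warm-started) at every
#'   trial point.  This walks the gauge valley that joint refinement cannot.
#' @param profile_outer,profile_inner iteration budgets of the profile
#'   stage.
#' @return a list of class \code{ga_config}.
#' @export
ga_config <- function(population = 80, generations = 150, tournament = 3,
                      p_crossover = 0.9, eta_crossover = 12,
                      p_mutation = 0.1, sigma0 = 0.15, sigma_final = 2e-4,
                      elitism = 2, seed = 1,
                      bound_angle = 10, bound_dtheta = 5, bound_trans = 20,
                      gauge_lambda = 1e-4,
                      gauge_scale = c(2, 2, 5, 5, 5, rep(20, 6)),
                      polish = TRUE, polish_rounds = 5,
                      profile = TRUE, profile_outer = 25, profile_inner = 60) {
  structure(as.list(environment()), class = "ga_config")
}

#' Self-calibrate the two-view gantry geometry
#'
#' Identifies the 11 device parameters of the secondary view (its two
#' positioner angles plus three detector rotations, three detector offsets
#' and three isocenter shifts) by genetic-algorithm minimisation of the 2D
#' reprojection mean square error over the sampled point correspondences.
#' The primary view is the posterior-anterior reference; the DICOM header
#' values of the secondary view seed the search box.
#'
#' @param q1,q2 n x 2 matrices (n >= 2) of corresponding detector points in
#'   mm (bifurcation points for trees, end-points for single branches).
#' @param base list of two \code{\link{gantry_pose}} objects built from the
#'   DICOM headers (distances, pixel spacing, nominal secondary angles).
#' @param config a \code{\link{ga_config}}.
#' @return object of class \code{xra_calibration}: optimal parameter vector,
#'   the calibrated secondary pose, the final MSE (mm^2), the per-generation
#'   best-MSE history, and the seed used.
#' @export
calibrate <- function(q1, q2, base, config = ga_config()) {
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  if (nrow(q1) < 2 || nrow(q2) < 2)
    stop("calibration needs at least 2 point correspondences")
  stopifnot(nrow(q1) == nrow(q2), inherits(config, "ga_config"))
  x0 <- .params_of_pose(base[[2]])
  half <- c(rep(config$bound_angle, 2), rep(config$bound_dtheta, 3),
            rep(config$bound_trans, 6))
  lo <- x0 - half; hi <- x0 + half
  if (any(hi <= lo)) stop("empty calibration search box")
  mse_fn <- function(x) reprojection_mse(x, q1, q2, base)
  obj <- function(x) mse_fn(x) +
    config$gauge_lambda * sum(((x - x0) / config$gauge_scale)^2)

  res <- withr_seed(config$seed, .run_ga(obj, lo, hi, x0, config))
  if (config$polish) {
    x <- res$best
    for (round in seq_len(config$polish_rounds)) {
      x <- stats::optim(x, obj, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-14))$par
      x <- stats::optim(x, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-14))$par
    }
    if (obj(x) < res$value) { res$best <- x; res$value <- obj(x) }
  }
  if (config$profile) {
    mis <- res$best[-(1:2)]
    ab0 <- res$best[1:2]
    # optimize angle OFFSETS so the simplex steps are ~0.1 degree
    prof <- function(dab) {
      op <- stats::optim(mis, function(m) obj(c(ab0 + dab, m)),
                         method = "BFGS",
                         control = list(maxit = config$profile_inner,
                                        reltol = 1e-12))
      mis <<- op$par
      op$value
    }
    po <- stats::optim(c(0, 0), prof, method = "Nelder-Mead",
                       control = list(maxit = config$profile_outer,
                                      reltol = 1e-10))
    # re-solve the inner problem at the returned optimum (the warm state
    # belongs to the last trial point, not necessarily the best one)
    prof(po$par)
    cand <- c(ab0 + po$par, mis)
    if (obj(cand) < res$value) { res$best <- cand; res$value <- obj(cand) }
  }
  structure(list(params = res$best,
                 pose1 = base[[1]],
                 pose2 = .apply_params(base[[2]], res$best),
                 mse = mse_fn(res$best), fitness = res$value,
                 history = res$history,
                 seed = config$seed, config = config),
            class = "xra_calibration")
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.run_ga <- function(obj, lo, hi, x0, cfg) {
  d <- length(lo)
  width <- hi - lo
  np <- cfg$population
  pop <- matrix(runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, width, "*"), 2, lo, "+")
  pop[1, ] <- x0                               # seed with the DICOM guess
  fit <- apply(pop, 1, obj)
  history <- numeric(cfg$generations)
  decay <- (cfg$sigma_final / cfg$sigma0)^(1 / max(cfg$generations - 1, 1))
  sigma <- cfg$sigma0
  for (g in seq_len(cfg$generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    elite_fit <- fit[ord[seq_len(cfg$elitism)]]
    # tournament selection of parents
    pick <- function() {
      cand <- sample.int(np, cfg$tournament)
      cand[which.min(fit[cand])]
    }
    kids <- matrix(0, np, d)
    i <- 1
    while (i <= np) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (runif(1) < cfg$p_crossover) {
        cr <- .sbx(p1, p2, cfg$eta_crossover)
        c1 <- cr[[1]]; c2 <- cr[[2]]
      } else { c1 <- p1; c2 <- p2 }
      kids[i, ] <- c1
      if (i + 1 <= np) kids[i + 1, ] <- c2
      i <- i + 2
    }
    # per-gene Gaussian mutation with decaying step
    mut <- matrix(runif(np * d) < cfg$p_mutation, np, d)
    step <- matrix(rnorm(np * d), np, d) * rep(width * sigma, each = np)
    kids <- kids + mut * step
    kids <- pmin(pmax(kids, rep(lo, each = np)), rep(hi, each = np))
    kfit <- apply(kids, 1, obj)
    # elitism replaces the worst offspring
    worst <- order(kfit, decreasing = TRUE)[seq_len(cfg$elitism)]
    kids[worst, ] <- elite
    kfit[worst] <- elite_fit
    pop <- kids; fit <- kfit
    history[g] <- min(fit)
    sigma <- sigma * decay
  }
  best <- which.min(fit)
  list(best = pop[best, ], value = fit[best], history = cummin(history))
}

# simulated binary crossover on one parent pair
.sbx <- function(p1, p2, eta) {
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(c1, c2)
}

#' @export
print.xra_calibration <- function(x, ...) {
  cat(sprintf("XRA gantry calibration: MSE = %.6g mm^2 (seed %d)\n",
              x$mse, x$seed))
  cat(sprintf("  secondary view: alpha = %.3f deg, beta = %.3f deg\n",
              x$params[1], x$params[2]))
  invisible(x)
}

#' @export
coef.xra_calibration <- function(object, ...) {
  p <- object$params
  names(p) <- c("alpha2", "beta2", "dtheta_x", "dtheta_y", "dtheta_z",
                "dO_x", "dO_y", "dO_z", "di_x", "di_y", "di_z")
  p
}

#' @export
summary.xra_calibration <- function(object, ...) {
  cat("Calibrated secondary-view parameters:\n")
  print(round(coef(object), 4))
  cat(sprintf("Final reprojection MSE: %.6g mm^2 after %d generations\n",
              object$mse, length(object$history)))
  invisible(object)
}

#' Construct a calibration object from known geometry
#'
#' Wraps exact (e.g. phantom ground-truth) poses in the calibration result
#' structure so that downstream matching and reconstruction can be run
#' without the optimisation step.
#'
#' @param pose1,pose2 the two \code{\link{gantry_pose}} objects.
#' @param mse the associated reprojection error (mm^2), default 0.
#' @return an \code{xra_calibration} object.
#' @export
known_calibration <- function(pose1, pose2, mse = 0) {
  structure(list(params = .params_of_pose(pose2), pose1 = pose1,
                 pose2 = pose2, mse = mse, history = numeric(0),
                 seed = NA_integer_, config = NULL),
            class = "xra_calibration")
}
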