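# ---------------------------------------------------------------------------
# End-to-end orchestration: phantom (or acquisitions) -> calibration ->
# gating -> centerlines -> surfaces -> tree mesh -> validation artifacts.
# ---------------------------------------------------------------------------

#' Reconstruct one branch surface from a two-view phantom or acquisition
#'
#' Convenience wrapper over \code{\link{reconstruct_centerline}},
#' \code{\link{build_patch}}, \code{\link{fit_cross_section}} and
#' \code{\link{assemble_surface}} for a branch observed in two views.
#'
#' @param c1,c2 2D centerline polylines (mm) in the two views.
#' @param borders1,borders2 lists of the two border polylines per view.
#' @param calib an \code{xra_calibration}.
#' @param q number of cross-section patches (default 30).
#' @param w circular samples per patch (default 16).
#' @param mode cross-section model; default "auto" picks circle for two
#'   views (ellipse needs 3+, polygon 6+ views).
#' @param t_range patch parameter range along the centerline; the small
#'   default inset keeps the 2D normals away from the polyline ends.
#' @param refine number of centerline refinement passes (default 1): the
#'   centerline is refit through the fitted cross-section centers and the
#'   patches rebuilt.  The first-pass centerline from point matching
#'   carries a depth bias at shallow inter-view angles (the dissimilarity
#'   is blind to motion along the rays); the cross-section fits, anchored
#'   on the measured borders, correct it.
#' @return list with \code{centerline} (a \code{branch_centerline}),
#'   \code{surface} (a \code{branch_surface}) and \code{patches}.
#' @export
reconstruct_branch <- function(c1, c2, borders1, borders2, calib,
                               q = 30, w = 16, mode = "auto",
                               t_range = c(0.02, 0.98), refine = 1) {
  rc <- reconstruct_centerline(c1, c2, calib)
  views <- list(
    list(c2d = rc$match$c1, borders = borders1, pose = calib$pose1,
         s_of_t = rc$s1_of_t),
    list(c2d = rc$match$c2, borders = borders2, pose = calib$pose2,
         s_of_t = rc$s2_of_t))
  if (mode == "auto") mode <- "circle"        # two views
  ts <- seq(t_range[1], t_range[2], length.out = q)
  build_all <- function(rcv, vws) {
    patches <- list()
    for (t in ts) {
      p <- build_patch(t, rcv, vws)
      if (!p$complete || is.null(p$points2d)) next
      p$fit <- fit_cross_section(p$points2d, mode)
      patches[[length(patches) + 1]] <- p
    }
    if (length(patches) < 2) stop("too few complete cross-section patches")
    patches
  }
  patches <- build_all(rc, views)
  for (pass in seq_len(refine)) {
    ctr3 <- t(vapply(patches, function(p) {
      cc <- if (p$fit$mode == "polygon") colMeans(p$fit$points) else p$fit$center
      p$center + cc[1] * p$frame$N + cc[2] * p$frame$B
    }, numeric(3)))
    s1v <- vapply(patches, function(p) views[[1]]$s_of_t(p$t), numeric(1))
    s2v <- vapply(patches, function(p) views[[2]]$s_of_t(p$t), numeric(1))
    crv <- fit_bspline(ctr3, 4, max(6, round(nrow(ctr3) / 3)))
    frames <- frenet_frames(crv, seq(0, 1, length.out = 100), method = "rmf")
    tb <- crv$tbar
    rc <- structure(list(curve = crv, samples = ctr3, frames = frames,
                         match = rc$match,
                         s1_of_t = function(t) approx(tb, s1v, xout = t,
                                                      rule = 2)$y,
                         s2_of_t = function(t) approx(tb, s2v, xout = t,
                                                      rule = 2)$y),
                    class = "branch_centerline")
    views[[1]]$s_of_t <- rc$s1_of_t
    views[[2]]$s_of_t <- rc$s2_of_t
    patches <- build_all(rc, views)
  }
  list(centerline = rc, surface = assemble_surface(patches, w = w),
       patches = patches)
}

#' Run the full reconstruction pipeline on a phantom specification
#'
#' Generates the phantom, calibrates the two views from the sampled points
#' (optionally skipping the optimisation when \code{use_ga = FALSE}, in
#' which case the header poses are trusted), gates the frame sequences when
#' present, reconstructs every branch centerline and lumen surface, meshes
#' the tree (or the single branch) and, since the ground truth is known,
#' writes a signed-deviation validation report.  All artifacts go to
#' \code{out_dir}.
#'
#' @param spec a \code{phantom_spec}.
#' @param out_dir output directory.
#' @param v,n_long mesh densities.
#' @param q,w surface densities.
#' @param use_ga run the genetic-algorithm calibration (default TRUE).
#' @param ga a \code{\link{ga_config}}.
#' @return invisibly, a list with the calibration, branches, mesh, quality
#'   and deviation report.
#' @export
run_pipeline <- function(spec, out_dir, v = 8, n_long = 30, q = 30, w = 16,
                         use_ga = TRUE, ga = ga_config()) {
  if (length(spec$poses) < 2)
    stop("the pipeline needs two views (primary + secondary)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logit <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)

  ph <- generate_phantom(spec)
  logit("phantom: %d branches, %d views", length(ph$branches),
        length(ph$views))

  q1 <- forward_project(ph$samples3d, spec$poses[[1]])
  q2 <- forward_project(ph$samples3d, spec$poses[[2]])
  calib <- if (use_ga) {
    base2 <- spec$poses[[2]]
    base2$dtheta <- base2$dO <- base2$di <- c(0, 0, 0)  # unknown a priori
    calibrate(q1, q2, list(spec$poses[[1]], base2), ga)
  } else known_calibration(spec$poses[[1]], spec$poses[[2]])
  jsonlite::write_json(list(params = calib$params, mse = calib$mse),
                       file.path(out_dir, "calibration.json"), digits = NA)
  logit("calibration: MSE %.6g mm^2", calib$mse)

  if (!is.null(ph$frame_sequences)) {
    gating <- gate_frames(ph$frame_sequences[[1]], ph$frame_sequences[[2]],
                          calib)
    jsonlite::write_json(list(pairs = gating$pairs, cost = gating$cost),
                         file.path(out_dir, "frame_pairs.json"), digits = NA)
    logit("gating: %d frame pairs", nrow(gating$pairs))
  }

  nb <- length(ph$branches)
  recon <- vector("list", nb)
  for (b in seq_len(nb)) {
    vw1 <- ph$views[[1]]; vw2 <- ph$views[[2]]
    recon[[b]] <- reconstruct_branch(vw1$centerlines[[b]],
                                     vw2$centerlines[[b]],
                                     vw1$borders[[b]], vw2$borders[[b]],
                                     calib, q = q, w = w)
    write_polyline_csv(recon[[b]]$centerline$samples,
                       file.path(out_dir, sprintf("centerline_%02d.csv", b)))
    write_curve_json(recon[[b]]$centerline$curve,
                     file.path(out_dir, sprintf("centerline_%02d.json", b)))
    write_surface_json(recon[[b]]$surface,
                       file.path(out_dir, sprintf("surface_%02d.json", b)))
    logit("branch %d: %d matched points, length %.2f mm", b,
          nrow(recon[[b]]$centerline$samples),
          bspline_length(recon[[b]]$centerline$curve))
  }

  mesh <- if (nb > 1 && !all(is.na(spec$parent))) {
    tr <- coronary_tree(lapply(recon, function(r)
      list(centerline = r$centerline, surface = r$surface)), spec$parent)
    trim_and_merge(tr, v = v, n_long = n_long)
  } else {
    mesh_branch(recon[[1]]$surface, n_long = n_long, v = v)
  }
  write_vtk_hex(mesh, file.path(out_dir, "tree_mesh.vtk"))
  write_inp_hex(mesh, file.path(out_dir, "tree_mesh.inp"))
  qual <- mesh_quality(mesh)
  logit("mesh: %d hexes, min scaled Jacobian %.4f", nrow(mesh$hexes),
        qual$min)

  # validation against the known truth
  truth <- list(
    vertices = do.call(rbind, lapply(ph$meshes, `[[`, "vertices")),
    faces = {
      off <- 0; fl <- list()
      for (m in ph$meshes) {
        fl[[length(fl) + 1]] <- m$faces + off
        off <- off + nrow(m$vertices)
      }
      do.call(rbind, fl)
    })
  test <- list(vertices = NULL, faces = NULL)
  off <- 0
  for (r in recon) {
    tm <- surface_to_mesh(r$surface, nu = 40, nv = 24)
    test$vertices <- rbind(test$vertices, tm$vertices)
    test$faces <- rbind(test$faces, tm$faces + off)
    off <- nrow(test$vertices)
  }
  dev <- signed_deviation(test, truth)
  jsonlite::write_json(c(dev$summary, dev$hausdorff[c("max", "mean")]),
                       file.path(out_dir, "deviation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stl_ascii(truth, file.path(out_dir, "ground_truth.stl"))
  write_stl_ascii(test, file.path(out_dir, "reconstruction.stl"))
  logit("deviation: mean |d| %.4f mm", dev$summary$mean_abs)

  invisible(list(phantom = ph, calibration = calib, branches = recon,
                 mesh = mesh, quality = qual, deviation = dev))
}
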