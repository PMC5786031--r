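# ---------------------------------------------------------------------------
# Acquisition ingestion and standard export formats.  Acquisitions are read
# from a plain-text sidecar header (JSON carrying the DICOM tag names) next
# to the pixel data (PNG frames or CSV matrices); poses, curves, meshes and
# reports round-trip through CSV/JSON/STL/VTK/INP.
# ---------------------------------------------------------------------------

#' Read an XRA acquisition
#'
#' Expects a directory with \code{header.json} holding the standard DICOM
#' fields (\code{PositionerPrimaryAngle}, \code{PositionerSecondaryAngle},
#' \code{DistanceSourceToDetector}, \code{DistanceSourceToPatient},
#' \code{ImagerPixelSpacing}, optionally \code{FrameRate}) and frame files
#' \code{frame_###.csv} (numeric matrices) or \code{frame_###.png}.
#'
#' @param path acquisition directory.
#' @param pixel_spacing optional length-2 override (mm/px) when the header
#'   lacks ImagerPixelSpacing.
#' @return list of class \code{xra_acquisition}: \code{pose},
#'   \code{frames}, \code{frame_rate}, \code{path}.
#' @export
read_acquisition <- function(path, pixel_spacing = NULL) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("missing header.json in ", path)
  h <- jsonlite::read_json(hf, simplifyVector = TRUE)
  need <- c("PositionerPrimaryAngle", "PositionerSecondaryAngle",
            "DistanceSourceToDetector", "DistanceSourceToPatient")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("header lacks mandatory tag(s): ",
                         paste(miss, collapse = ", "))
  ks <- h$ImagerPixelSpacing
  if (is.null(ks)) {
    if (is.null(pixel_spacing))
      stop("header lacks ImagerPixelSpacing; supply pixel_spacing=")
    warning("using pixel_spacing override")
    ks <- pixel_spacing
  }
  pose <- gantry_pose(alpha = h$PositionerPrimaryAngle,
                      beta = h$PositionerSecondaryAngle,
                      sod = h$DistanceSourceToPatient,
                      sid = h$DistanceSourceToDetector,
                      kappa = rep(as.numeric(ks), length.out = 2))
  fcsv <- sort(list.files(path, "^frame_.*\\.csv$", full.names = TRUE))
  fpng <- sort(list.files(path, "^frame_.*\\.png$", full.names = TRUE))
  frames <- if (length(fcsv)) {
    lapply(fcsv, function(f) as.matrix(read.csv(f, header = FALSE)))
  } else if (length(fpng)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is needed to read PNG frames")
    lapply(fpng, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    })
  } else list()
  structure(list(pose = pose, frames = frames,
                 frame_rate = if (!is.null(h$FrameRate)) h$FrameRate else NA,
                 path = path),
            class = "xra_acquisition")
}

#' Write an acquisition header sidecar
#' @param pose a \code{gantry_pose}. @param path target directory.
#' @param frame_rate frames/s.
#' @export
write_acquisition_header <- function(pose, path, frame_rate = 15) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(PositionerPrimaryAngle = pose$alpha,
                            PositionerSecondaryAngle = pose$beta,
                            DistanceSourceToDetector = pose$sid,
                            DistanceSourceToPatient = pose$sod,
                            ImagerPixelSpacing = pose$kappa,
                            FrameRate = frame_rate),
                       file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(path, "header.json"))
}

#' @rdname polyline_io
#' @export
write_polyline_csv <- function(points, path) {
  colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Polyline CSV round trip
#' @param points n x 2/3 matrix. @param path file path.
#' @name polyline_io
#' @export
read_polyline_csv <- function(path) {
  as.matrix(read.csv(path))
}

#' Write a B-spline curve descriptor as JSON
#' @param curve a \code{bspline_curve}. @param path file path.
#' @export
write_curve_json <- function(curve, path) {
  jsonlite::write_json(list(order = curve$k, knots = curve$knots,
                            control = curve$control),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(control = j$control, knots = j$knots, k = j$order,
                 tbar = NULL), class = "bspline_curve")
}

#' Write a branch surface descriptor (control net + knots) as JSON
#' @param surf a \code{branch_surface}. @param path file path.
#' @export
write_surface_json <- function(surf, path) {
  jsonlite::write_json(list(k = surf$k, l = surf$l, w = surf$w,
                            uknots = surf$uknots,
                            control = lapply(seq_len(dim(surf$control)[1]),
                                             function(i) surf$control[i, , ])),
                       path, digits = NA)
  invisible(path)
}

#' Write a triangle mesh as ASCII STL
#' @param mesh list(vertices, faces). @param path file path.
#' @export
write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid coroxr", con)
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; cc <- V[F[i, 3], ]
    n <- cross3(b - a, cc - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("    vertex %g %g %g", cc[1], cc[2], cc[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid coroxr", con)
  invisible(path)
}

#' Write a hexahedral mesh as legacy ASCII VTK
#' @param mesh a \code{hex_mesh}. @param path file path.
#' @export
write_vtk_hex <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$hexes)
  writeLines(c("# vtk DataFile Version 3.0", "coroxr hexahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  writeLines(apply(mesh$hexes, 1, function(h)
    paste(c(8, h - 1), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)
  invisible(path)
}

#' Write a hexahedral mesh as an Abaqus-style INP deck
#' @param mesh a \code{hex_mesh}. @param path file path.
#' @export
write_inp_hex <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D8", con)
  writeLines(vapply(seq_len(nrow(mesh$hexes)), function(i)
    paste(c(i, mesh$hexes[i, ]), collapse = ", "), character(1)), con)
  invisible(path)
}

#' Write a triangle mesh as Wavefront OBJ
#' @param mesh list(vertices, faces). @param path file path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
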