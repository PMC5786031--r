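# coroxr

Three-dimensional reconstruction and structured hexahedral meshing of
coronary arteries from two uncalibrated X-ray angiography (XRA) views.

X-ray angiography is the standard imaging modality of interventional
cardiology, but every acquisition is a 2D projection. Given two views of
the contrast-filled coronary tree — biplane, or two monoplane runs —
`coroxr` recovers a 3D model and delivers it as a structured, conforming
all-hexahedral mesh ready for downstream simulation (coronary flow, FFR,
virtual stenting), with no manual remeshing. It is aimed at researchers in
cardiovascular image-based modelling.

The chain:

* **Image formation.** A ray-casting model of the C-arm: gantry rotation
  `M = Ry(β)·Rx(α)`, source `F = M(0,0,−d_sod)ᵀ + Δi`, detector point
  `P = O + R_Δθ M (ΔO + (p_u,p_v,0)ᵀ) + Δi`, with explicit detector
  misalignment rotations `Δθ`, detector offset `ΔO` and isocenter shift
  `Δi`. Forward projection inverts the mapping exactly; two rays
  triangulate by their common-perpendicular midpoint.
* **Self-calibration.** The 11 secondary-view parameters
  `{α₂, β₂, Δθ, ΔO, Δi}` are identified by a genetic algorithm minimizing
  the two-view reprojection mean square error
  `F(XA) = Σᵢ Σⱼ |q_ij − q̂_ij(Q_j)|² / n` over a handful of point
  correspondences, with a weak gauge-fixing prior toward the DICOM header
  values (the model is over-parameterized; see the methods vignette).
* **Temporal gating and centerline matching.** Both use optimal
  subsequence bijection: the minimum-cost strictly monotone one-to-one
  pairing with skip cost `√((k−q−1)² + (l−w−1)²)·ξ + δ(k,l)`; for gating
  `ξ = min+std` of the row minima of `δ`, for centerlines
  `ξ = √2·ε*_min` (the calibration error). One-to-one by construction,
  unlike dynamic time warping (included as a baseline).
* **Centerline and lumen surface.** Matched pairs triangulate to 3D,
  fitted by clamped cubic B-splines (Cox–de Boor, chord-length knots) with
  rotation-minimizing frames; border silhouette rays give cross-section
  boundary points, fitted by circles (2 views), ellipses (3+) or polygons
  (6+), skinned into a tensor-product NURBS surface
  `S(u,v) = Σᵢ Σⱼ B_ij N_{i,k}(u) M_{j,l}(v)` (periodic in v).
* **Structured meshing.** O-grid cross-section patches (center node, inner
  ring at 45% radius, outer ring: `2v+1` nodes, `3v/2` quads) swept into
  hexahedra; trees are merged at bifurcations by symmetric miter-plane
  trimming with exact node sharing — conforming and watertight, with
  per-element scaled-Jacobian reporting.
* **Phantom and metrics.** A synthetic ground-truth generator (tube trees,
  exact silhouette projections, cardiac-motion frame sequences) plus
  signed surface deviation, Hausdorff distance and centerline-length
  agreement statistics.

## Worked example

Reconstruct a 1.5 mm phantom vessel from two views 55° apart and mesh it:

```r
library(coroxr)

pose1 <- gantry_pose(0, 0)                      # posterior-anterior reference
pose2 <- gantry_pose(55, 10)                    # LAO 55, CRA 10
branch <- branch_line(start = c(-5, -20, 2), dir = c(0.15, 1, 0.1),
                      length = 40, radius = 1.5)
phantom <- generate_phantom(phantom_spec(list(branch), NA,
                                         list(pose1, pose2), seed = 3))

calib <- known_calibration(pose1, pose2)        # or calibrate(q1, q2, ...)
rec <- reconstruct_branch(phantom$views[[1]]$centerlines[[1]],
                          phantom$views[[2]]$centerlines[[1]],
                          phantom$views[[1]]$borders[[1]],
                          phantom$views[[2]]$borders[[1]], calib)
print(rec$centerline)
#> Reconstructed branch centerline: 30 matched points, length 38.40 mm
print(rec$surface)
#> Branch lumen surface: 30 x 16 control net, orders (4, 4)

mesh <- mesh_branch(rec$surface, n_long = 30, v = 8)
summary(mesh)
#> Hexahedral mesh: 527 nodes, 360 elements
#> Scaled Jacobian: min 0.7071, mean 0.8516

deviation <- signed_deviation(surface_to_mesh(rec$surface, 50, 24),
                              phantom$meshes[[1]])
print(deviation)
#> Surface deviation: mean +0.0000 / -0.0001 mm, max +0.0000 / -0.0001 mm, sd 0.0000 mm
#> Hausdorff: max 1.5688 mm, mean 0.0554 mm, sd 0.2417 mm
```

The reconstructed surface lies within a ten-thousandth of a millimetre of
the true tube (the Hausdorff maximum reflects only the shorter axial
extent of the reconstruction, whose patches inset 2% from the polyline
ends). The mesh minimum of 0.7071 is the intrinsic corner bound of the
O-grid pattern — `sin 135°` at the core-quad inner corners — not a defect
of this particular mesh; `mesh_quality(mesh, at = "centroid")` evaluates
the integration-point form instead. Trees are assembled with
`coronary_tree()` / `phantom_tree()` and meshed with `trim_and_merge()`;
`run_pipeline()` orchestrates phantom → calibration → gating →
reconstruction → meshing → validation and writes all artifacts
(CSV/JSON/STL/VTK/INP). A thin command-line front end lives in
`inst/cli/coroxr.R`.

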