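---
title: "Reconstructing and meshing coronary arteries from two X-ray angiography views"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and meshing coronary arteries from two X-ray angiography views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroxr)
```

## The problem

X-ray angiography (XRA) remains the workhorse imaging modality of
interventional cardiology, but each acquisition is a 2D projection.  When
two views of the contrast-filled coronary tree are available — either from
a biplane system or from two monoplane runs — the 3D lumen can be
recovered, provided the relative geometry of the two views is known
accurately enough.  The DICOM header records the positioner angles
(LAO/RAO, CRA/CAU), the source-to-isocenter (SOD) and source-to-detector
(SID) distances and the imager pixel spacing, but gantry sag, table motion
and detector play make those values only approximately true.

`coroxr` implements an end-to-end procedure: a ray-casting model of image
formation with explicit misalignment terms, self-calibration of the
two-view geometry from a handful of point correspondences, temporal gating
of the two frame sequences, centerline reconstruction by elastic partial
matching, NURBS lumen-surface reconstruction from the projected borders,
and structured hexahedral meshing of complete trees — the mesh being the
point: structured, conforming all-hex output can go straight into
downstream hemodynamic or structural simulation without manual remeshing.

## Image formation model

One view is described by a `gantry_pose`: angles $(\alpha, \beta)$,
distances $d_{sod} < d_{sid}$, pixel spacing $\kappa$, and the misalignment
terms — detector rotations $\Delta\theta$, detector translation $\Delta O$
and isocenter shift $\Delta i$.  The gantry rotation is
$M = R_y(\beta)\,R_x(\alpha)$ (orthonormal by construction); the source is
$F = M\,(0,0,-d_{sod})^T + \Delta i$ and a detector point $(p_u, p_v)$ in
millimetres about the image center sits at

$$P \;=\; O + R_{\Delta\theta} M \left(\Delta O + (p_u, p_v, 0)^T\right) + \Delta i ,$$

with $O = M\,(0,0,d_{sid}-d_{sod})^T$.  `forward_project()` inverts this
mapping exactly (ray-plane intersection); the round trip is identity to
machine precision, which the test-suite checks on random poses including
misalignments.  Two detector points from the two views define two rays
whose common-perpendicular midpoint is the reconstructed 3D point
(`triangulate()`); the segment length is the triangulation gap.

Two conventions were open and are fixed here: pixel indices are converted
to millimetres about the image *center* (the projection-plane origin lies
on the principal ray), and the misalignment terms are attached to the
secondary view only, the primary view being the ideal posterior-anterior
reference — exactly the eleven parameters the calibration estimates.

## Self-calibration and its identifiability limit

`calibrate()` minimizes the two-view reprojection mean square error: every
corresponding point pair (bifurcations for trees, end-points for single
branches) is triangulated under the candidate geometry, ray-traced back
onto both detectors, and the squared residuals of both views are summed
and divided by the number of pairs.  The optimizer is a real-coded genetic
algorithm (population 80, 150 generations, tournament selection of size 3,
SBX crossover with probability 0.9, per-gene Gaussian mutation with
probability 0.1 and a geometrically decaying step, elitism 2), fully
deterministic given its seed.

Working on the problem revealed a structural property worth knowing: the
eleven-parameter model is *over-parameterized*.  A small change of the
positioner angles can be compensated exactly — not approximately — by the
detector rotation, detector translation and isocenter terms, because the
objective re-triangulates the 3D points under each candidate geometry and
therefore only measures two-view consistency.  Box-constrained profiling
confirms the null space: with the angle fixed half a degree off its true
value, the remaining nine parameters can drive the MSE to $10^{-23}$.  Two
consequences follow.  First, a pure minimizer of the reprojection error
returns an arbitrary representative of a whole solution manifold, with
angle errors of several degrees at MSE below $10^{-3}\,mm^2$.  Second, any
meaningful angle recovery must say *which* representative is wanted.  The
package resolves the gauge with a weak quadratic prior toward the DICOM
header values, weighted by physically motivated per-parameter scales
(angles 2°, the accuracy of the header readout; detector rotations 5°;
translations 20 mm, the scale of gantry sag), with weight $10^{-4}$ —
small enough never to bias the identifiable directions measurably.  After
the GA, a quasi-Newton/simplex refinement and a profile stage (outer
search on the two angles, inner re-optimization of the nine misalignment
terms) walk the curved gauge valley that neither the GA nor joint local
refinement can traverse.  On a noiseless phantom with misalignments of a
few millimetres and degrees this recovers the angles to about 0.1°; the
residual angle uncertainty grows toward
$\left|\Delta O\right|/(d_{sid}-d_{sod})$ radians as the injected
translations approach the search bounds, which is an information limit of
the objective, not of the optimizer.

## Partial matching: gating and centerline correspondence

Both the temporal and the spatial correspondence problems are solved by
the same engine, optimal subsequence bijection (OSB, `osb_match()`): the
minimum-cost strictly monotone one-to-one pairing of two sequences, where
jumping from pair $(q,w)$ to $(k,l)$ costs
$\sqrt{(k{-}q{-}1)^2 + (l{-}w{-}1)^2}\,\xi + \delta(k,l)$ and virtual
source/sink elements at $(0,0)$ and $(m{+}1,p{+}1)$ carry no cost of their
own.  Unlike dynamic time warping (provided as `dtw_match()` for
comparison), OSB may *skip* elements of either sequence — outlier frames,
or over-segmented centerline tails — and never produces one-to-many
pairs.  The implementation is an exact dynamic program over the DAG,
verified against exhaustive enumeration on hundreds of random instances up
to 8×8; cost ties break toward paths with more pairs.

For **gating**, $\delta(k,l)$ is the reprojection MSE of pairing frame $k$
of view 1 with frame $l$ of view 2 under the calibrated geometry, and the
skip penalty is derived from the dissimilarity matrix itself:
$\xi = \min_q \min_w \delta + \mathrm{std}_q(\min_w \delta)$ (population
standard deviation).  For **centerline matching**, $\delta(r,t)$ is the
unnormalized two-view residual of the triangulated candidate point and
$\xi = \sqrt2\,\varepsilon^*_{\min}$, the calibration error.  With exact
synthetic geometry $\varepsilon^*_{\min}$ vanishes and every skip would be
free, so below $10^{-9}\,mm^2$ the gating-style penalty takes over — a
degenerate case real data never reaches.

## Centerline, surface, and a refinement pass

Matched point pairs are triangulated and fitted with a clamped cubic
B-spline (Cox–de Boor recursion, chord-length knots; the basis is verified
against an independent implementation to $10^{-12}$).  Moving frames are
rotation-minimizing (double reflection) by default, with true
Frenet–Serret frames available where the curvature is defined; straight
runs always fall back to parallel transport so the frames never flip.

Each cross-section patch is built from the views' borders: the 2D
centerline normal is intersected with both borders, the intersections are
lifted onto the positioned detector, and each lifted point defines a
silhouette ray from the focal spot.  The boundary point is the foot *on
that ray* of the common perpendicular between the ray and the centerline
tangent line — the point where the grazing ray touches the vessel.  (The
foot on the tangent line itself projects back onto the centerline and
carries no radial information; for an exact cylinder the ray-foot sits at
exactly the tube radius, which the tests confirm to 0.02 mm.)  Projected
into the normal–binormal plane, two views give four points per patch,
fitted by an algebraic least-squares circle; three or more views admit a
direct least-squares ellipse, six or more a polar-sorted polygon — the
recommended modes at those view counts, since two-view ellipses become
sheared below ~30° of angular separation.

Because the matching dissimilarity is blind to motion *along* the rays,
the first-pass centerline carries a systematic depth bias when the views
are separated by only 20–30°, which displaces the ray feet and inflates
radii by a few percent.  `reconstruct_branch()` therefore refits the
centerline through the fitted cross-section centers — which are anchored
on the measured borders — and rebuilds the patches once (configurable).
This single pass reduces the mean absolute surface deviation of a 1.5 mm
phantom cylinder at 20° separation from 0.044 mm to about $5\times10^{-5}$
mm, and it is what makes the reconstruction essentially independent of the
inter-view angle over 20–90°.

The patches, resampled at `w` shared polar angles (no twist, because the
frames are rotation-minimizing), are skinned into a tensor-product
B-spline surface: periodic cubic interpolation in the circular direction,
clamped interpolation in the longitudinal direction.  The surface passes
exactly through every sampled boundary point; between the circular sites a
16-point periodic cubic deviates from a true circle by about $10^{-4}$ of
the radius, which sets the meaning of "exact" in the tests.

## Structured meshing and its quality bounds

A cross-section patch of circular subdivision $v$ (a multiple of 4) has a
center node, an inner ring at 45% of the outer radius and the outer ring —
$2v{+}1$ nodes and $3v/2$ quads ($v/2$ core + $v$ ring).  Sweeping
successive patches yields $3v/2$ hexahedra per layer.  At a bifurcation,
three miter planes through the junction point (normals $u_p{+}u_1$,
$u_p{+}u_2$, $u_1{-}u_2$) trim the incident branches; one shared contour
per interface is built by projecting and averaging the nearest removed
contours, with the two "fold" samples of each ring meeting on the common
line of the three planes.  Node-exact sharing of the resulting terminal
patches makes the merged mesh conforming and watertight, which the test
suite audits by face incidence (every interior quad face on exactly two
elements).  The circular sampling of each branch is rotated (and, between
two junctions, linearly twisted) so that a core-quad boundary sample lands
on the fold line — measured against the surface's own circular origin.
Rings whose outer nodes reach within 30% of a layer spacing of a trim
plane are removed, so junction layers never fold back.

Two intrinsic quality bounds deserve emphasis, because they are properties
of the committed pattern, not defects of a particular mesh.  First, on an
ideal circular section the inner ring is a regular polygon, so the core
quads subtend 135° at their odd inner-ring corners: the corner-minimum
scaled Jacobian of even a perfect straight-cylinder mesh is
$\sin 135° = 0.7071$ (ring elements score 0.9239).  Second, the
child–child miter plane is tilted from the cross-section by 90° minus the
half-angle between the children, so junction-adjacent elements are bounded
near the sine of that half-angle — roughly 0.25–0.5 at physiological
bifurcation angles.  A graded ring-blending transition was evaluated and
rejected: the corner metric measures the absolute obliqueness of the cut,
not its increment, so grading cannot raise it.  `mesh_quality()` therefore
reports both the corner-minimum metric (the common verification
definition, range $[-1,1]$, default) and the centroid-evaluated normalized
Jacobian (the single-integration-point metric of FEA codes), which is
insensitive to the fixed 135° corner and scores above 0.9 away from
junctions.  Published claims that such meshes keep "Jacobian > 0.85"
are only reproducible under integration-point-style definitions; under the
corner-minimum definition the pattern itself caps the figure at 0.71, and
a two-bifurcation tree at 30 longitudinal subdivisions and $v = 8$ scores
about 0.2–0.3.  The package reports what it measures.

## The phantom: what it emulates, and what it does not

All validation runs on `generate_phantom()`: tube trees from line, arc and
helix generators with per-branch radii and optional Gaussian stenoses;
exact perspective projections of the centerlines; borders as true
silhouette tangency points (so magnification is present and a projected
diameter is $2 d_{sid}\tan(\arcsin(r/D))$, not a scaled diameter); optional
rasterized frames; and frame sequences of the deforming sample points.
The cardiac motion model is two-harmonic with per-point random directions
and phases — periodic but time-asymmetric, so no two distinct phases
produce the same configuration — with sub-frame timing jitter (sd 0.2
frames) because the two views are acquired on different heartbeats, and
0.5 px Gaussian jitter on the projected points.  These are the study
conditions for the gating experiments; with a noise-free single-harmonic
phantom the skip penalty is degenerate (all row minima near zero) and OSB
legitimately matches almost nothing.  Everything is deterministic given
the specification seed.

What the phantom does not emulate: respiratory drift, beam physics
(scatter, beam hardening), pincushion distortion (flat panels assumed),
vessel overlap and foreshortening pathologies, or anatomically realistic
tree topology.  Passing tests on the phantom therefore demonstrate the
geometric correctness of the chain, not clinical performance.

## Numerical choices

* Fast marching solves the Eikonal equation with second-order upwind
  differences and an analytically initialized 13×13 source
  neighbourhood; uniform-speed arrival times match Euclidean distance to
  0.2% on a 200×200 grid.  Vesselness uses scales 2–6 px (step 0.5),
  blobness 0.5 and a relative structureness cutoff of 0.1, on the
  inverted image.
* Borders are Dijkstra shortest paths on the 8-connected
  gradient-magnitude graph, with the centerline nodes removed so the two
  borders cannot cross it; border end-points are the strongest edge
  response along the end normals within 20 px.
* Centerlines are resampled to 100 arc-length points before matching;
  the dissimilarity matrix is computed in closed form for all pairs at
  once.
* Default surface/mesh densities: 30 patches per branch, 16 circular
  samples, cubic orders; meshing at $v = 8$, 30 longitudinal
  subdivisions.  The acceptance computations use a five-branch,
  two-bifurcation tree (~1600 elements, seconds of runtime) and 20-branch
  length studies; these sizes were chosen to keep every experiment
  desk-scale while leaving the statistics stable.
* Ties in the OSB dynamic program break toward more pairs, then smaller
  indices; the standard deviation in the skip penalty is the population form.

## Known limitations

Trifurcations are not supported (a bifurcation has exactly two children).
Ellipse fitting from two views is deliberately refused (five-point
minimum).  The calibration angle estimate is prior-resolved along the
gauge direction, as discussed above.  The mesher assumes branches are long
enough to trim — a branch shorter than about three layer spacings past its
junction clearance raises an error naming the branch.  4D (multi-frame)
reconstruction runs frame pairs independently; no temporal coherence is
enforced beyond the gating itself.
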