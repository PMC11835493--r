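---
title: "Measuring skin stretch with stereo digital image correlation: models and methods"
author: "dermastretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skin stretch with stereo DIC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dermastretch)
```

## The measurement problem

When a joint flexes, the trunk bends or a facial muscle contracts, the skin
above it stretches and compresses in two dimensions along its surface. The
resulting strain field is a candidate signal for proprioception: stretch-
sensitive mechanoreceptors respond to skin elongation of as little as 1%.
Quantifying natural skin stretch therefore requires a full-field, two-
dimensional, millimetre-resolution measurement over large curved patches of
skin — not a one-dimensional marker pair.

`dermastretch` implements the optical measurement chain for this problem:
an ink speckle pattern applied to the skin is photographed by calibrated
camera pairs in a relaxed reference pose and one or more deformed poses;
subset-based digital image correlation (DIC) matches speckle patches across
cameras and poses; matched points are triangulated into 3-D surfaces;
per-triangle membrane strain between poses yields principal and orthogonal
stretch; and plane-projected maps provide the summary statistics (stretch
maps at 1 mm resolution, distance profiles, stretch gradients, percentile
summaries, axial orientation statistics).

Because the package is validated without any photography, it also contains
a first-class synthetic scene generator: speckle textures with physically
scaled dots, analytic deformation fields with closed-form ground-truth
strain, and a pinhole renderer. Every accuracy figure the package reports
is measured by running the full chain on these synthetic scenes and
comparing against the analytic ground truth.

## Speckle patterns

`generateSpeckle()` emulates ink speckle patterns with three parameters:
dot diameter (default 1.27 mm), target ink area fraction (default 0.65) and
"dot variation" (default 0.75). Dots are placed uniformly at random — with
overlap permitted, matching the behaviour of commercial speckle generators,
which target a density rather than a packing — until the measured covered
raster fraction reaches the target. Density is measured post hoc on the
raster (fraction of pixels more than half covered), and the realized ink
fraction stays within ±5 percentage points of the target for densities up
to 0.7. Densities of 0.9 or more are refused: with overlapping dots the
covered fraction approaches such targets exponentially slowly.

The dot-variation parameter is not given a definition by the upstream
pattern-generation tools, so the package commits to one reading: each dot's
diameter is drawn uniformly from `diameter * [1 - variation, 1]`, a
downward jitter below the nominal diameter. Patterns are rendered
anti-aliased at a configurable raster scale (default 8 px/mm), normalized
to [0, 1] with ink dark, and are bit-identical for identical seeds.

## Deformation models and their ground truth

Each `DeformationModel` couples a map from material coordinates (u, v) in
mm to deformed 3-D positions with the analytic strain field it induces:

* `identityModel()` and `rigidMotionModel()` — zero stretch everywhere, the
  null conditions for the noise floor;
* `uniaxialStretch(m)` — `(u, v) -> ((1+m) u, v, 0)`; principal stretch
  `100 m` percent along u, orthogonal zero. `m = 0.33` is the headline
  validation condition;
* `rampStretch(g)` — local stretch growing linearly along u at `g` percent
  per cm, with positions given by the exact integral of the local stretch,
  so the ground-truth field is exactly linear (used to validate the
  stretch-gradient statistic; the 5 %/cm preset matches the gradient scale
  observed on the trunk);
* `bulge(A, R)` — a radial Gaussian bump (sigma = R/2) of apex height A,
  coupled with an in-plane radial expansion `rho(r) = r (1 + beta g(r))`,
  `beta = kappa A / R` (kappa = 0.3), the way an inflating membrane carries
  material outward. Ground truth follows from the surface metric:
  circumferential stretch `rho/r` and radial stretch
  `sqrt(rho'(r)^2 + z'(r)^2)`. Positive amplitude emulates a puffed cheek
  (orthogonal stretch positive near the apex), negative amplitude an inward
  pouting contraction (orthogonal stretch negative) — the disambiguation
  signature between the two facial poses.

The bulge ground truth is verified in the tests against dense numerical
differentiation of the map to below 0.1 percentage points.

## Rendering

`renderView()` renders by inverse mapping: each pixel's ray is intersected
with the deformed surface by a vectorized three-unknown Newton iteration on
(u, v, ray parameter), and the recovered material coordinate samples the
speckle texture with bicubic (cubic-convolution, a = -0.5) interpolation.
There is no lighting or shading model — the patterns are high-contrast ink,
and the physical validation protocol imaged flat printouts — and the only
imaging imperfection modelled is additive Gaussian intensity noise (default
sd 0.01 of the [0, 1] range) plus the change of viewing angle. Real
failure modes such as smudged ink, body hair and gloss are *not* emulated;
the test suite constructs a smudge fixture (a blurred stripe) only to check
that quality flags fire. Passing the synthetic validation therefore
demonstrates the correctness and noise behaviour of the processing chain,
not robustness to every physical artefact.

## Camera model, calibration and triangulation

Cameras are pinhole models with optional radial distortion. The fixed
convention: right-handed coordinates, the camera looks down its +z axis,
pixel (0, 0) is top-left, pixel centers at integer coordinates, and a world
point projects via `p_cam = R X + t`. The default synthetic rig places two
cameras 200 mm apart at 300 mm from the patch — one calibrated pair of the
four-camera acquisition square — with focal length 3000 px so a central
pixel covers roughly 0.1 x 0.1 mm, the footprint of the real acquisitions.
Which two of the four cameras form the pair is a configuration choice, not
a commitment.

`calibrateStereo()` implements the standard checkerboard workflow: saddle-
point corner detection (Hessian-determinant response, Foerstner subpixel
refinement, homography-based grid ordering), per-camera closed-form
initialization from homographies, then a joint Levenberg-Marquardt
refinement (via `minpack.lm`) of both cameras' intrinsics, the shared
relative pose and per-view board poses. Distortion defaults to zero for
synthetic scenes; two radial terms can be estimated when fitting real
images. On noiseless synthetic boards the reprojection error is far below
0.1 px and the recovered baseline is within 1% of truth; with 2 px corner
noise the reprojection error sits in the 2–4 px range of real calibrations.

Triangulation is linear midpoint triangulation — the point minimizing the
summed squared distance to the back-projected rays — matching the
per-pair workflow; there is no four-camera bundle adjustment. Per-point
residuals are mean reprojection distances, and rays subtending less than
0.1 degrees are flagged degenerate.

## Digital image correlation

Matching is subset-based with the full-scale processing parameters: square
subsets of half-width 60 px ("patch radius") spaced 10 px apart, so
neighboring subsets overlap heavily. The similarity criterion is
zero-normalized cross-correlation (ZNCC), which is exactly invariant to
affine intensity changes; the upstream tooling says only
"cross-correlating", and ZNCC is the standard robust choice. The subset
shape is square rather than circular; at these radii the difference is
immaterial and the square allows the integral-image accelerations used in
the integer search.

Matching proceeds coarse-to-fine:

1. a sparse integer ZNCC pass on 4x block-averaged images absorbs the large
   inter-camera and inter-pose displacements (search radius defaults to a
   quarter of the image width for pose matching). The coarse subsets are
   deliberately small (half-width 8 coarse px), which keeps them correlated
   even at 33% strain, and the coarse displacement field is cleaned by a
   3 x 3 median filter — a neighborhood-consensus step that removes isolated
   wrong peaks without the score gate that would also discard strongly
   strained content;
2. a dense integer pass with a reduced subset (half-width 15 px) searches
   ±10 px around the interpolated coarse prediction; exact ties break
   toward the smallest displacement magnitude, then lexicographically;
3. a quadratic fit of the ZNCC surface around the peak plus a local
   least-squares plane fit of neighboring integer displacements seed an
   inverse-compositional Gauss-Newton refinement with a first-order
   (affine) subset shape function and bicubic interpolation, run at the
   full 60 px radius. Convergence requires the parameter-update norm
   (gradient terms scaled by the subset radius) to fall below 1e-4 px
   within 50 iterations; failures are flagged `diverged`.

The affine shape function is sufficient for the smooth warps the chain is
validated on; first-order seeding from the neighboring displacement field
is what lets the optimization start inside its convergence basin even at
33% strain. An epipolar-band restriction for cross-camera search was
considered and replaced by this coarse-to-fine initialization, which
subsumes it without requiring calibration at matching time. Matches with
final ZNCC below 0.8 are flagged `low_score`; subsets whose integer-stage
peak is already at noise level (below 0.3) are flagged without spending
Gauss-Newton iterations. Flat (zero-variance) subsets get score 0.

`trackPoseChain()` anchors every tracked point on camera 1's reference
grid and matches it into camera 2 at reference, camera 1 at the deformed
pose and camera 2 at the deformed pose; points surviving all three matches
are triangulated in both poses. If fewer than half of the textured subsets
survive, the run aborts — mirroring real acquisitions where reliable image
correlations could not be found.

The pipeline restricts the subset grid to a region of interest: subsets
fully inside the projection of the speckled patch. A subset straddling the
patch boundary mixes moving material with static background, so no single
displacement explains its content; real DIC analyses draw the same region
of interest around the stamped pattern. The synthetic scenes derive the
region from the projected patch corners inset by one subset radius.

## Membrane strain

For each mesh triangle, both configurations are expressed in their own
orthonormal in-plane frames; the 2 x 2 in-plane deformation gradient F maps
reference edge vectors to deformed edge vectors and the Green-Lagrange
tensor is `E = (F'F - I) / 2`. With eigenvalues `e1 >= e2` of E, the
principal stretch ratios are `lambda_i = sqrt(1 + 2 e_i)` and the package
reports engineering stretch `100 (lambda_i - 1)` percent. This is the only
reading under which a uniaxial 33% elongation prints as "33%": the
benchmark right triangle with legs (1,0) and (0,1) deformed to (1.33,0),
(0,1) yields principal stretch 33, orthogonal 0. The closed-form identity
`F = diag(1.2, 1.1) => E = diag(0.22, 0.105)`, stretches (20, 10), area
ratio 1.32 is asserted in the tests, as is exact rigid-motion invariance
(to 1e-9) and cyclic relabeling invariance.

Strain lives in each triangle's own plane — a membrane assumption; bending
is not penalized. The principal orientation is the e1 eigenvector rotated
back into the 3-D reference frame and stored axially (theta and theta+180
identical) with a canonical sign. The area ratio is |det F| and satisfies
`areaRatio = (1 + principal/100)(1 + orthogonal/100)` for in-plane
deformation; `100 (areaRatio - 1)` is the local skin area change used in
the area-change maps. Raw per-triangle values are reported; an optional
k-ring smoothing (`smoothStrain()`) exists but is off by default, since
whether the upstream tooling smooths before reporting is unknown.

Meshing uses the regular DIC grid directly: each complete grid quad splits
into two triangles along a fixed diagonal (on a regular lattice this is a
Delaunay triangulation up to cocircular ties), triangles with an edge over
3x the median are pruned as bridges across holes, and sub-1e-6 mm^2
triangles are dropped as degenerate. At the full-scale geometry (1 mm grid
spacing) mean triangle areas land in the 0.5–2.4 mm^2 range of real
tracked patches.

## Plane projection and map statistics

The best-fitting plane minimizes squared orthogonal distance to the
reference vertices (principal-axes fit). The in-plane strain fraction —
reported as 97% on average on real skin patches — has no published
formula, so the package defines it as the stretch-magnitude-weighted mean
in-plane component of the principal directions: each triangle's unit
principal direction d contributes `|d - (d.n)n|` weighted by
`|principal stretch|`. Exactly planar scenes give 1.0 by construction.

`resampleGrid()` projects triangle centroids into plane coordinates and
takes area-weighted means per cell at 1 mm resolution (the mapping
resolution used throughout); orientations average axially via the
doubled-angle vector mean; empty cells within two cells of occupied ones
are filled by nearest neighbor, everything else is masked. Resampling
conserves the area-weighted mean within 0.5 percentage points on all test
scenes.

The stretch gradient is defined as the mean magnitude of the central-
difference spatial gradient of the stretch map, in percent per cm — the
"direction-resolved versus magnitude" ambiguity is resolved toward the
mean gradient magnitude, which reproduces linear ramps exactly and is
insensitive to the patch orientation. Distance profiles project unmasked
cells onto the straight line through two anchors and bin by projected
distance; straight-line plane distance approximates geodesic distance and
will understate it on strongly curved patches. Percentiles are
area-weighted with linear interpolation between order statistics at
midpoint plotting positions. Axial orientation statistics double the
angles, compute the weighted circular mean and circular standard deviation
`sqrt(-2 ln R)`, and halve back; the statistic is invariant to flipping
any subset of orientations by 180 degrees. Whether published angular SDs
were computed on raw triangles or the resampled grid is not stated; both
paths exist (`orientationStats()` on a `StrainField` or a `GridMap`) and
the grid is the default.

## Validation conditions and problem sizes

`runValidationSuite()` reproduces the four synthetic validation
conditions: undeformed/same view, undeformed/rotated view (10–20 degrees,
default 15), 33% stretch/same view and 33% stretch/rotated view, reporting
mean absolute principal- and orthogonal-stretch errors in percentage
points and the mean 3-D point error in mm against analytic ground truth.

The package's desk-scale study conditions, chosen once: a 40 x 30 mm flat
patch, texture at 8 px/mm, two cameras with a 200 mm baseline at 300 mm
and 700 x 500 px frames at the real 0.1 mm/px central footprint, image
noise sd 0.01, and the full-scale DIC settings (radius 60 px, spacing
10 px). Because the pixel footprint matches the real acquisitions, the DIC
parameters carry over unscaled; only the patch and frame are smaller
(roughly four hundred tracked points inside the region of interest rather
than several thousand), keeping a full condition to a few seconds of CPU.
The validation suite and the reconstruction study average each condition
over three seeds.

`runReconstructionStudy()` measures 3-D accuracy in the calibrated-camera
regime: checkerboard corner observations with ~2 px Gaussian noise put the
calibration reprojection RMS near 3 px (the regime of the real
calibrations, where the residual is dominated by corner observation noise
rather than camera-model error), the DIC chain runs on undeformed,
stretched and rotated-view acquisitions, and tracked points triangulated
with the *fitted* cameras are compared to ground truth after best-fit
rigid (Kabsch) alignment — a calibrated frame is defined only up to a
rigid motion of the true world frame. Directly corrupting the camera
parameters until triangulation residuals reach 3 px would instead model a
geometrically inconsistent rig and inflate point errors several-fold; the
calibration-based construction matches how the 3 px figure arises in
practice.

## Numerical choices and degenerate inputs

* One interpolation family throughout: cubic convolution with a = -0.5 for
  rendering, DIC refinement and fixture warping.
* Integer-match ties break toward the smallest displacement magnitude,
  then lexicographically — asserted identically in the brute-force oracle.
* Flat subsets, out-of-frame subsets, singular Gauss-Newton Hessians and
  degenerate (collapsed) triangles are flagged, never silently dropped.
* All randomness flows from a single integer seed per scene; pipeline
  outputs are byte-identical across reruns of the same configuration.
* Rotations serialize as quaternions, scenes and cameras as YAML sidecars,
  matches and strains as CSV, meshes as ASCII PLY pairs, maps as plain
  text with YAML headers.

## Limitations

Synthetic validation bounds the chain's algorithmic error, not its
behaviour on real skin: specular gloss, hair, smudged ink, autofocus
drift and non-static poses are outside the model. Human-subject summary
values (mean trunk stretches, angular SDs, repeatability correlations)
require the deposited imaging data and are represented here only by
property-level analogues on synthetic scenes. Strain is membrane-only; no
constitutive skin model, thickness or volume estimate is attempted, and
no statistical inference across participants is provided.
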