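---
title: "Non-model-based left-atrial volumetry from sparse cine slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-model-based left-atrial volumetry from sparse cine slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriarecon)
```

## The measurement problem

Left-atrial (LA) dilatation is a prognostic marker across many cardiac
diseases, and LA volume is the quantity clinical guidelines ask for.
Measuring it by cine MR traditionally requires either a full multi-slice
stack (many breath-holds, misregistration between them) or a model-based
shortcut such as the bi-plane area-length formula, which assumes an
ellipsoidal chamber. A fast acquisition can instead collect a handful of
2D cine slices — typically two long-axis and three short-axis views in
arbitrary orientations — in a single breath-hold. The question this package
addresses is how to turn those few, arbitrarily oriented closed contours
per cardiac phase into a chamber volume without a geometric model, and how
to derive LA function (reservoir, conduit, booster pump) from the resulting
time–volume curve.

## The reconstruction

Each slice carries a closed endocardial contour in its own image plane,
located in space by the DICOM plane metadata (origin of pixel (0,0),
row/column direction cosines, pixel spacing; LPS patient coordinates,
0-based indices addressing pixel centres). On each plane the contour
defines an indicator: $+1$ inside, $-1$ outside, with the contour as its
zero set. The package carries this indicator either literally (`binary`
mode) or as the in-plane signed distance clamped to $[-\tau, \tau]$ and
scaled to $[-1, 1]$ (`signed_distance`, the default) — the same zero set,
but smoother across it.

The indicator must then be extended from the planes into all of space so
its zero level set can be extracted as a surface. Two interpolation
engines are provided:

* **`projection`** — the inverse out-of-plane-distance blend
  $F(p) = \sum_j w_j f_j(\pi_j(p)) / \sum_j w_j$ with
  $w_j = 1/(d_j^{power} + \varepsilon^{power})$, where $d_j$ is the
  distance to plane $j$ and $\pi_j$ the orthogonal projection onto it.
  It reproduces each plane's field exactly on that plane (queries within
  $10^{-6}$ mm snap to the plane value) and blends smoothly in between.
  Its weakness is geometric: wherever the nearest slice is the *wrong*
  informant — most visibly beyond the outermost short-axis slice, in the
  azimuthal gap between the two long-axis planes — the nearest section is
  extruded outward, and no choice of power or clamp repairs it, because
  the error is in the value being blended, not in the weights. On the
  noise-free sphere phantom this inflates the volume by roughly 10%. The
  engine is retained because its on-plane contract is exact and it is the
  natural baseline; it also behaves well on dense parallel stacks.
* **`rbf`** (default) — a variational implicit surface: the contours are
  resampled, their vertices become zero-level constraints, points offset
  along the in-plane normals become signed constraints (value $\pm 1$ in
  binary mode, the clamped signed distance otherwise, always evaluated
  from the true in-plane signed distance so a misestimated normal cannot
  flip a constraint), and a triharmonic radial basis function
  ($\varphi(r)=r^3$) with a linear polynomial tail is interpolated through
  them. This is the classic cross-section surface reconstruction approach;
  it uses the long-axis contours to close the chamber roof and mitral
  region, which is exactly the information the projection blend ignores.
  With 40 constraints per contour the noise-free phantom error is a few
  tenths of a percent.

The interpolated indicator is sampled on an isotropic grid (1 mm default)
over the padded bounding box of all contours; the outermost node layer is
forced negative so the surface always closes. The zero surface is
extracted by marching tetrahedra on the Kuhn 6-tetrahedron cube
decomposition. That decomposition is translation-invariant, so neighbouring
cubes agree on shared faces and the mesh is watertight by construction;
vertices on shared grid edges are deduplicated exactly (by edge key, not by
coordinate tolerance), and every triangle is oriented outward against the
local inside reference. Nodes with value exactly zero count as outside,
making the mesh deterministic. Volume is the divergence-theorem sum
$\left|\sum_f \det(a_f, b_f, c_f)\right|/6$, reported in ml.

Grid resolution trades accuracy for time: on an analytic sphere the volume
error falls from about 2% at 4 mm to 0.5% at 2 mm and 0.13% at 1 mm, and
the default problem sizes (1 mm grids for static frames, 1.5 mm for
34-frame cines) keep a full validation run in the low minutes on one core.

## Contours in, contours smoothed

Binary masks from upstream segmentation tools are traced at the 0.5
iso-level with subpixel marching squares; the largest connected component
is kept by default (`error_if_multiple` is available). Contours are then
smoothed by periodic penalized least squares in the Fourier basis — a
discrete second-difference penalty on both coordinates, the smoothing
parameter chosen by generalized cross-validation, plus up to three
bisquare reweighting passes to resist outlier vertices. Periodicity means
closure and vertex count are preserved and there are no endpoint
artifacts; with `smoothing = 0` the operation is the identity, and on an
already-smooth contour the GCV choice is effectively the identity too.
The smoothing actually applied is recorded in the reconstruction metadata.

## The model-based comparator

The modified bi-plane area-length volume is
$V = 0.848 \, A_{4ch} A_{2ch} / \left((L_{4ch}+L_{2ch})/2\right)$,
with the areas from the two orthogonal long-axis views and each length the
maximum distance from the mitral valve mid-position to the opposite wall.
The constant is kept at the printed 0.848 rather than $8/(3\pi)$; for an
ellipsoid sliced through its principal axes the formula therefore returns
exactly $0.848/(8/3\pi) = 0.99906$ of the analytic volume, which the test
suite asserts to machine precision. Lengths are measured on contours
resampled to at least 256 vertices (discretization below 0.1 mm), on the
smoothed contours (the choice is configurable; smoothing is the default
throughout the package). The mitral mid-position is an explicit input —
for phantom data it is carried in the dataset's ground-truth block and
snapped to the nearest contour vertex; there is no automatic valve
detection.

## Synthetic phantoms and the orientation study

The generator builds implicit LA-shaped solids with analytic reference
volumes: ellipsoids with semi-axis ratio 1 : 1.2 : 1.5 (large 54 ml,
small 51 ml), a sheared ellipsoid (oblique connection, 61 ml, shear 0.45
of the long axis), a sphere (55 ml) and an ellipsoid bent along a 40 mm
circular arc (aortic-root impression, 70 ml). Shear is volume-preserving,
and the toroidal bend has Jacobian $(R+x)/R$, linear in the bend
coordinate, so bending about the centroid preserves volume exactly —
all five reference volumes are closed-form, and a 0.5 mm voxel-integration
oracle cross-checks them in the tests to better than 0.05%.

Each phantom is sliced by five planes at 1.5 mm pixel spacing, emulating
the acquisition: two orthogonal long-axis planes crossing the mitral
mid-point along the acquired axis, three short-axis planes perpendicular
to that axis at the quartiles of the shape's projected extent (the
operator covers the proximal, mid and distal chamber as seen). Three
orientation strategies per shape: row 1 aligned and perpendicular, row 2
aligned with short-axis planes tilted 20°, row 3 with the acquired long
axis rotated 25° away from the mitral-disc normal — the analogue of
planning on a standard ventricular view. The angles are parameters, not
constants; the defaults are recorded in every dataset's metadata, along
with the noise level and seed (vertex noise is Gaussian in mm, and all
randomness flows through one seeded generator).

Cine phantoms scale the base shape self-similarly so the enclosed volume
tracks a prescribed LA cycle — filling from $V_{min}$ to $V_{max}$
(40% of the cycle), passive emptying to the pre-contraction shoulder
$V_{preA}$ (to 75%), active emptying back to $V_{min}$ — built from
cosine segments so the curve is smooth and the shoulder is a genuine flat
point. The plane set is posed once and fixed for all frames, as in a real
acquisition. This is pure global scaling: it validates the volume pipeline,
not regional wall motion, conduction patterns or through-plane motion of
real atria, and passing it says nothing about segmentation quality on real
images — contours here are exact sections of the implicit shape.

## Time-volume curves and functional indices

From the per-frame volumes the curve is treated as periodic. The maximum
and the (cyclically following) minimum are read directly; the
pre-contraction frame is either supplied, or located as the flattest
interior point (minimal central-difference $|dV/dt|$) strictly between
maximum and minimum, excluding two frames at each end; a curve without a
clear shoulder is flagged low-confidence, and `NA` encodes an atrium that
no longer contracts (then the pre-contraction volume coincides with the
minimum and the passive fraction is 100%). The indices are plain
arithmetic on the three landmark volumes: total (conduit) emptying
$V_{max}-V_{min}$, passive $V_{max}-V_{preA}$, active $V_{preA}-V_{min}$,
total emptying fraction $100\,(V_{max}-V_{min})/V_{max}$, passive/active
fractions as percent of total, and, when the LV stroke volume is given,
the "passive LA flow" $SV_{LV} - (V_{max}-V_{min})$. Phase rates are mean
rates (phase volume over phase duration, ml/ms), not peak $dV/dt$; a
peak-rate variant would need a smoother derivative estimate than 30 ms
sampling supports, and the mean-rate definition is the one consistent with
the bundled worked examples. These formula choices were frozen after
verifying that they reproduce every derivable cell of the bundled
three-patient table at printed precision.

## Agreement statistics

Method comparison uses Bland-Altman analysis: mean and SD of paired
differences with limits of agreement at mean ± 2 SD (the convention of the
validation study's figures, rather than 1.96 SD), percent differences
relative to the pairwise mean — a convention verified against the bundled
table's percent column — and the regression of measurement on reference.
The orientation-by-method question is answered by a two-way
repeated-measures ANOVA on the 2 × 2 within-subject design (alignment ×
reconstruction method, subjects = phantom shapes), fitted with
`stats::aov` error strata; for a 2 × 2 design the interaction test is
algebraically a paired t-test on the per-subject double difference, and
the test suite asserts that identity exactly. Endocardial border
sharpness is the mean over 8 radial profiles of the reciprocal 20–80%
edge-transition width (1/pixels, capped at 1, profiles sampled at
0.25-pixel steps in a ±10-pixel window around the wall crossing); rays
leaving the image are dropped and flagged.

## Numerical choices and degenerate inputs

* Direction cosines deviating by less than $10^{-3}$ from orthonormality
  (rounded DICOM headers) are re-orthonormalised; beyond that the plane is
  rejected.
* Inside/outside uses the even-odd rule with boundary points counted as
  inside; indicator ties at grid nodes count as outside. Both rules make
  results deterministic.
* A single contoured plane is an error; parallel-only plane sets are an
  error below three slices and a warned-but-processed degenerate stack from
  three on.
* Empty phantom-plane intersections are flagged (`NULL`), not errors:
  short-axis planes may legitimately miss the apex.
* Frames with missing contours are flagged in the curve, never
  interpolated.
* The RBF system carries a $10^{-9}$ ridge and unit-scaled coordinates for
  conditioning; constraint points closer than $10^{-3}$ mm are merged.

## Limitations

The package reconstructs from contours; it does not segment images, and
everything downstream inherits segmentation error silently. The phantom
suite demonstrates correctness of the geometry pipeline under exact
contours — real-image accuracy is bounded by the contours it is given.
The projection engine's end-slice extrusion is documented above and it is
not the default. Mesh quality (aspect ratios, feature preservation) is not
a goal: the enclosed volume is the deliverable, and marching tetrahedra on
a 1 mm grid serves that purpose.
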