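---
title: "Synthetic video generation and evaluation for insect pose estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic video generation and evaluation for insect pose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickgen)
```

## Overview

`stickgen` builds annotated synthetic top-view videos of a walking stick
insect and scores keypoint predictions against the automatic ground
truth. The pipeline is: joint angles → forward kinematics → geometric
augmentation → ray-cast rendering → 22-point annotation → evaluation
with confidence-based exclusion → non-parametric statistics. This
vignette is the package's account of the underlying model, the choices
that were genuinely open, and what the tests do and do not demonstrate.

## Body model and forward kinematics

The body is a chain of five trunk segments (head, pro-, meso-,
metathorax, abdomen) and six legs, each a serial chain of a lumped
coxa+trochanter, femur, tibia and tarsus, rendered as cylinders with
spheres at the joints. All lengths are in millimetres; the body frame
has x anterior, y left, z up, the animal centred at the origin and the
ground at z = 0.

Three angles per leg drive the chain:

* `alpha` (rad) — protraction(+)/retraction(−) about the vertical axis
  at the coxa;
* `beta` (rad) — levation(+)/depression(−) of the femur about the
  horizontal leg axis;
* `gamma` (rad) — interior femur–tibia angle (`gamma = pi` is a
  straight leg), so the tibia's elevation in the leg plane is
  `beta - (pi - gamma)`.

This is the minimal degree-of-freedom set that reproduces all 18 leg
landmarks of a straight-walking animal; a richer chain (separate
thorax–coxa rotations, tarsus joints) would not change any landmark the
pipeline tracks. Segment lengths are preserved exactly along the chain
(the test suite checks conservation at 1e-9 relative tolerance), scaling
the geometry commutes with the kinematics, and mirror symmetry holds by
construction.

The 22 tracked landmarks are the CxTr, FeTi and TiTa joints of all six
legs plus four trunk/head stations. Which four trunk points are tracked
is genuinely underdetermined at the 22-point budget, so the choice is a
`body_geometry` field (`trunk_landmarks`); the default is head anterior
tip, pro–meso boundary, meso–meta boundary, meta–abdomen boundary.
Tarsi and abdomen are *rendered but not tracked*: the tarsus extends the
tibia direction beyond the TiTa joint and is clamped to the ground plane
(z ≥ 0), the abdomen continues the metathorax axis rearward.

Default dimensions approximate an adult female (total body length 80 mm,
femora 11–14 mm). Cylinder and sphere radii are appearance choices of
this package, stated in `body_geometry()`, not measured values.
`scale_geometry()` multiplies radii along with lengths so a scaled
animal keeps its proportions.

## Camera and units

The virtual camera is a pinhole 200 world units above the ground plane
looking straight down, image 640 × 480 px, field of view 69.4°. The
field-of-view axis is not self-evident from those constants alone; the
package interprets it as *horizontal* by default and exposes
`fov_axis = "vertical"`/`"diagonal"` for reinterpretation. Pixel
coordinates have their origin at the top-left corner, x right, y down,
pixel centres at integer + 0.5.

The ground-plane resolution in mm/px is *not* derived from the camera:
with millimetre world units the focal length implied by 69.4°/200 units
does not reproduce the quoted 0.28 mm/px, so the base resolution is
treated as a measured constant supplied to `resolution_at_scale()`
(default 0.28 mm/px at scale 1, giving 0.56 and 0.187 mm/px at scales
0.5 and 1.5). Pixel errors convert to millimetres by multiplication
(`px_to_mm()`).

## Augmentation semantics

`sample_transforms()` draws, independently per frame: translation
uniform over the square [−30, 30] px per axis; rotation uniform over the
half-open interval [0, 2π) (measure-equivalent to the closed interval)
or over a discrete set; scale uniform over {0.5, 0.7, 1.0, 1.3, 1.5}.
`apply_transform()` realises them so that ground truth is exact:

* **scale** multiplies the posture's coordinates and radii about the
  origin (equivalent to scaling segment lengths before kinematics);
* **rotation** adds to the camera roll, so projections rotate about the
  image centre;
* **translation** moves the camera's in-plane target by
  `t * height / f_px`, making the projected shift equal the requested
  pixel amount exactly for ground-plane points (for points above the
  ground the shift differs by the perspective factor `H/(H - z)`, which
  is the physically correct behaviour of a camera shift).

Annotations are always recomputed *after* the transform, so the ground
truth matches the rendered frame by construction; the test suite
additionally verifies the pixel-space commutation law
(scale about centre, rotate by −θ, shift) at 1e-6 px on planar scenes.

The experiment builders encode the three standard designs: the seven
nonempty transformation subsets (1,600 frames, 200 training frames
each, the TRS video doubling as the benchmark test set), eight
cumulative 45° rotations (800-frame base videos; training set *k* draws
200 frames uniformly over the union of videos 1..k — uniform rather
than stratified sampling is a deliberate, logged choice since either
reading is defensible), and the pre-training grid of 8 rotations × 5
scales. The paper-scale pre-training selection is 8,000 frames; since
the length of the source video is not fixed by the design, the builder
uses an 8,000-frame video with per-frame transforms drawn uniformly
from the 40-combination grid and selects all of them.

## Rendering and visibility

Rendering is analytic ray casting: each pixel's ray is intersected with
every sphere and finite open cylinder (a per-primitive conservative
screen bounding box and a z-buffer keep it fast), the nearest hit wins,
and shading is Lambertian from the camera direction over an ambient
floor on a uniform mid-gray background. There is no texture, lens
distortion, motion blur or sensor noise — deliberately: the synthetic
videos isolate geometric variation, and the renderer is deterministic
and bit-reproducible, which encoded video would not be. Cylinder end
caps are not rendered; every cylinder end is covered by a joint sphere.

A landmark is visible iff its projection lies inside the image and the
camera ray meets no body primitive strictly nearer than the landmark.
Since landmarks sit at joint centres *inside* their own spheres,
primitives that geometrically contain the landmark (its joint sphere
and the segments meeting there) are exempt from its occlusion test;
the clearance tolerance is 1e-6 world units. Invisible landmarks keep
their coordinates and are flagged, and the evaluation layer counts
(never silently drops) their exclusions.

## Gait generator

The built-in generator emulates the statistical structure of
straight-walking joint-angle recordings: a tripod phase pattern
({L1, R2, L3} in antiphase to {R1, L2, R3}), period 40 frames at a
nominal 50 Hz (a 0.8 s step cycle), duty cycle 0.75, and a piecewise
waveform — a slow linear retraction ramp during stance and a faster
half-cosine swing return with femur levation and tibia flexion — so
that tarsi meet the ground and legs occlude one another as in real
top-view footage. Amplitudes (±0.35 rad about pair-specific midpoints)
are realistic for slow walking. Optional seeded Gaussian jitter adds
frame-to-frame variability (default off).

What it does *not* emulate: inter-step variability, turning, climbing,
antennal movement, or the exact angle statistics of any recorded trial.
Tests passing on generated gaits therefore demonstrate the pipeline's
correctness (geometry, annotation, bookkeeping), not transfer to any
particular animal's kinematics. For real recordings,
`read_joint_angles()` ingests delimited angle tables (one row per
frame, `deg` or `rad` declared in a header comment, unknown columns
ignored with a message).

## Evaluation and statistics

`evaluate_predictions()` computes per-(frame, feature) Euclidean pixel
errors and excludes entries whose confidence is below the cut-off
(default 0.10, overridable). Because "average pixel error" is quoted as
a mean in running text and as medians in figures, the report carries
mean, median, IQR and SD side by side. Per-feature tables sort by
increasing SD and tag each feature with its proximal-to-distal group
(head/thorax, coxae, femur–tibia, tibia–tarsus; configurable).

`scoremap_argmax()` reduces a stride-8 confidence grid to the centre of
its brightest bin; ties are broken by row-major scan order and flagged,
and an all-zero map returns confidence 0 with a degenerate flag.

The statistical battery wraps the standard tests where R provides them
(`friedman.test`, `wilcox.test`) behind interfaces matched to the
blocked feature-by-model design; fully tied Friedman input returns
statistic 0 / p 1 rather than NaN. `mannwhitney_p()` is implemented
directly from the closed form
`z = (U + 0.5 − n1·n2/2) / sqrt(n1·n2·(n1+n2+1)/12)`, `p = Φ(z)`
(mirrored above the mean): the one-sided continuity-corrected normal
approximation is fixed deliberately, because that is the variant that
reproduces reported rank-sum p-values from published (U, n1, n2)
triples to three significant figures — the package's acceptance script
recomputes exactly this. Exhaustive sign-enumeration and rank-formula
oracles in the test suite pin the wrappers at small n.

`mock_predictor()` stands in for a trained network so the harness is
testable without any learning: truth plus isotropic Gaussian noise
(mean error `σ√(π/2)`, the Rayleigh mean — recovered within 3 standard
errors at 10⁴ entries in the tests), optional mislocation to another
landmark's position, and an optional low-confidence fraction. It makes
no claim to emulate network error *magnitudes*; learned-model error
levels depend on training and are out of scope.

## Numerical choices and degenerate inputs

* Training-set size uses `floor(fraction × n)` (10% of 286 frames → 28).
* Zero-length segments collapse landmarks without error; zero-length
  tibia directions leave the tarsus at the TiTa joint.
* Points at or behind the camera plane are flagged invalid, never
  silently projected.
* Transform draws, gait jitter, training splits and the mock predictor
  all run under locally scoped seeds (caller RNG state is restored), so
  identical spec + seed reproduces annotation files bit for bit.
* Annotation export: the DeepLabCut-compatible dialect (three-row
  scorer/bodyparts/coords header, x/y pair per body part) blanks
  invisible landmarks by default (`blank_invisible = FALSE` keeps
  them); the internal flat CSV preserves everything including
  visibility. Both round-trip losslessly at full precision.

## Problem sizes used in the checks

The test suite exercises the full designs' *arithmetic* (7/8/40-run
grids, 1,600- and 800-frame specs) but generates pixels only at small
scale: a 100-frame fully transformed video is rendered and evaluated
end to end, statistical recovery checks use ~10⁴ prediction entries,
and round-trip properties run on 100 random small datasets. These sizes
were chosen as the smallest that make the targeted failure modes
visible; the generators scale linearly for full-size runs.

## Known limitations

* No photometric augmentation, texture or camera noise — transfer to
  real video rests on fine-tuning, not on photorealism.
* One body plan; other species require a different `body_geometry`.
* The renderer's cylinders are open-ended (joint spheres cover the
  ends), so isolated cylinders viewed exactly end-on show a hole.
* HDF5 annotation containers are not written; the CSV dialects carry
  the same information.
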