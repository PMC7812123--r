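---
title: "Comparing the brain hull with the endocast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the brain hull with the endocast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Endocasts — replicas of the inner surface of the bony braincase — are the only
direct evidence of brain morphology in extinct taxa. Whether the furrows
imprinted on an endocast faithfully record the position of the cerebral sulci,
and how closely the endocranial surface follows the brain surface, has to be
established on extant individuals for whom both an MRI of the brain and a CT of
the cranium exist. `endocastr` implements that comparison as an unattended
pipeline and, because paired clinical scans cannot be redistributed, ships a
synthetic phantom generator with exact ground truth so that every stage is
testable.

The pipeline follows the workflow of quantitative brain/endocast studies:

1. **Modality registration and segmentation.** The MRI and CT volumes are
   rigidly registered by normalized mutual information; the *brain hull* (a
   simplified envelope of the brain that bridges fine cortical detail while
   keeping sulcal depressions) and the endocast are extracted by
   deformable-sphere segmentation and resampled to a fixed face budget.
2. **Sulcus detection and labelling.** Sulcal imprints are detected on both
   surfaces as *ravine lines* — curves where the minimal principal curvature
   attains an extremum along its own curvature line — and labelled against a
   reference curve set.
3. **Surface and curve comparison.** The brain hull is aligned to the endocast
   (rigid + uniform scale), then deformed onto it by a smooth kernel
   deformation; the labelled brain curves are transported through the same
   deformation and compared to the endocast curves with a mean closest-point
   distance and a 10 mm matching criterion, yielding count statistics, an
   extrapolated per-curve distance map and a surface displacement map.

## The phantom and what it does (not) emulate

`make_phantom()` builds a star-shaped "brain": an ellipsoid (default semi-axes
80 x 65 x 55 mm, adult-human scale) with a flattened base, carved by `n_sulci`
(default 10) groove arcs drawn from a seeded catalogue on the direction sphere.
Arcs live in a polar band away from both the flattened base and the superior
cap, and are rejected unless pairwise separated by at least twice the groove
width (default 6 mm), which keeps the 10 mm matching threshold meaningful —
it corresponds to the maximum distance between neighbouring sulci. Grooves have
a parabolic cross-section with maximal depth `groove_depth` (default 4 mm);
the ground-truth curve of each groove runs at mid-depth along its centerline.

The "endocast" is the same surface offset outward by `shell_thickness`
(default 2 mm, the dura/CSF gap), with groove depth attenuated by
`depth_attenuation` (default 0.4), a fraction `drop_fraction` (default 0.2) of
sulci absent entirely, the superior cap (within `cap_angle`, default 35°, of
+z) inflated by `superior_smoothing` (default 3 mm) and carrying a midline
sagittal-sinus ridge (`sinus_ridge_height`, default 2 mm). This reproduces, in
a parameterized way, the empirically reported pattern: good brain/endocast
correspondence laterally and basally, systematic mismatch superiorly along the
sinus. The CT volume is posed under a known rigid + uniform-scale modality
transform (default 5 mm-scale translation, 5° rotation, scale 1.02) and the
two volumes carry different intensity profiles with independent Gaussian noise,
so NMI registration is exercised non-trivially.

Defaults were chosen once, at realistic anatomical scale (voxel size 2 mm is
within the clinical range of the motivating data; grooves must span at least
two voxels). The phantom does **not** emulate anatomically realistic cortical
folding, vascular/meningeal structures beyond the single ridge, or scanner
artefacts (bias fields, geometric distortion). Passing tests therefore
demonstrate that the *geometry processing* is correct and recoverable under
noise, attenuation and partial data — not that detection thresholds are tuned
for clinical images.

## Numerical and design choices

**NMI registration.** NMI is fixed to the bounded Studholme form
\((H(A)+H(B))/H(A,B)\) on a 64-bin (32 by default in the registration) joint
histogram, min-max scaled over the overlap. The optimizer is derivative-free:
a coarse translation grid, then a rotation grid, then repeated Nelder-Mead
restarts over the 6 rigid degrees of freedom. Both volumes are box-smoothed
(two radius-1 passes) for the metric only; on near-binary volumes this removes
spurious local optima of the subsampled NMI without moving its maximizer, and
recovery of a known 4/-3/2 mm + 5° offset is then well under 0.1 mm / 0.1°.
The capture range at the defaults is about ±8 mm / ±9°.

**Shrink-wrap.** The seed surface is a subdivided icosahedron (uniform valence,
no pole artifacts), deformed by a clamped intensity force along vertex normals
blended with Laplacian smoothing. The default isovalue for mask-based hulls
sits slightly below midrange, biasing the surface a fraction of a voxel
outward so the hull encloses the voxel mask; smoothing weight 0.25 leaves
grooves two voxels wide clearly visible as depressions, while 0.6 and above
bridges them. Convergence is declared when the largest vertex displacement
falls below 0.01 mm.

**Mesh resampling.** Budgets are met exactly (midpoint subdivision up, then
shortest-edge midpoint collapse down, guarded by the manifold link condition
and a normal-flip check), because the face count is part of the comparison
protocol. On a sphere decimated tenfold the radial error stays below 1%.

**Curvature and ravines.** Principal curvatures come from a local cubic
height-field fit over a geodesic-like neighbourhood (default radius 2.5 mean
edge lengths); the extremality coefficient is the directional derivative of
each principal curvature along its own direction, read off the cubic terms.
Convexity w.r.t. the outward normal is positive, so groove floors have
strongly negative minimal curvature. Ravine tracing links extremality zero
crossings across triangles; the +-direction ambiguity of principal directions
is resolved per edge by sign alignment, triangles with three crossings keep
the two strongest, and chains whose endpoints fall within `join_gap` (default
two edge lengths — keep it below the sulcal spacing) are bridged, countering
the fragmentation inherent to crest-line tracing. The default curvature
threshold is the 75th percentile of |kmin| over the mesh (scale-adaptive);
detection is deterministic, but crossings that sit exactly at a threshold can
differ across rigid motions of the input at floating-point precision, which is
why equivariance holds at polyline level rather than bitwise.

**Deformation model.** The brain-hull-to-endocast map is the Euler flow (10
steps) of a stationary velocity field held by Gaussian-kernel control points
on a regular grid over the source bounding box — the simplest member of the
large-deformation family that satisfies the contracts this pipeline needs:
zero momenta give the identity exactly, the flow is smooth at the kernel scale
(default 15 mm, larger than the sulcal spacing so curves transport
coherently), and at the returned settings no face inverts. Full geodesic
shooting would add a state-dependent momentum ODE without changing any
downstream statistic here, since only the pairwise map and its action on
curves are used. The data term is a varifold distance (Gaussian spatial
kernel, default 5 mm; orientation-insensitive, hence robust to inconsistent
winding), normalized by the varifold norm of the target; the regularizer is
the mean kernel kinetic energy of the momenta (weight 1e-4). Momenta are
optimized by gradient descent with a backtracking line search from a
deterministic zero start, so the energy trace is non-increasing by
construction. Desk-scale defaults (about 1,000 control points; registration
meshes decimated to 2,000 faces in the pipeline) keep the contracts
resolution-independent; the ~100,000-control-point regime of production runs
is reached by configuration only.

**Matching statistics.** The curve distance is directional — for each point of
an *endocast* curve, the minimum point-to-segment distance to all same-label
(possibly fragmented) brain curves, averaged along the endocast curve — and a
curve matches when this mean is strictly below 10 mm (a distance of exactly
10 mm does not match). `NS_EB` counts endocast curves failing the criterion,
i.e. `TC_E - NC_EB`; published tables whose NS-EB column is not that
complement are still consumable by `summarize_reports()`, which treats counts
as inputs. Summary means are rounded half-up to integers because the reference
tables print integers. The distance map is an inverse-distance-weighted blend
of matched curves' mean distances within one matching radius (so it can never
overshoot the per-curve inputs); vertices nearest an unmatched curve are
sentinel-masked. The displacement map is the exact point-to-triangle distance
from endocast vertices to the deformed hull, stored raw with a 5 mm clipped
copy for rendering.

**Pipeline determinism.** One run seed fans out to per-stage seeds through a
fixed affine-mod scheme, so any stage can be rerun from its on-disk inputs
with the same result; reruns are bit-identical on the summary outputs. In the
pipeline, detected curves that remain `"unlabeled"` after reference-based
assignment are excluded before matching: on phantoms every real groove has a
reference, so unlabeled fragments are noise by construction.

## Problem sizes used by the tests

The shipped tests run the full pipeline on the default 10-sulcus phantom
(volumes around 90–110 voxels per axis at 2 mm), segment at 20,480 faces
resampled to 20,000, register on 2,000-face decimations with 600 control
points, and verify detection recall over a 10-seed catalogue; analytic
fixtures (spheres, cylinders, translated spheres) are used wherever a closed
form exists. The 100,000-face budget is exercised exactly once per run, as the
default of `resample_mesh()`.

## Known limitations

- The phantom's star-shaped geometry cannot represent overhanging anatomy;
  all downstream math is geometry-agnostic, but recall numbers on phantoms do
  not transfer to clinical scans.
- `carve_groove()` sweeps a ball of radius `width/2` along the inward-swept
  path, so its effective depth is `depth + width/2`; the phantom's analytic
  indent (exact depth) is used for ground truth instead.
- Crest-line fragmentation is mitigated by gap bridging, not eliminated;
  counts of *curves* (as opposed to labelled sulci) depend on mesh resolution.
- The rigid NMI optimizer is derivative-free and intended for the near-aligned
  clinical setting; it is not a global registration.
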