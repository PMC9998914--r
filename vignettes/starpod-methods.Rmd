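---
title: "Star-convex seed phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-convex seed phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starpod)
```

This vignette is the package's own account of the science it implements:
the representations and procedures, the tunable parameters with their
defaults and units, what the synthetic phantom does and does not emulate,
and the numerical and design choices made where more than one convention
was defensible. Everything quantitative stated here is computed by the
test suite or the acceptance script; nothing is quoted from elsewhere.

## The problem

A dried seed pod scanned by X-ray micro-CT is a stack of 2D trans-axial
slices forming a 3D grayscale volume, axis order `(Z, Y, X)` with the
pod's long axis along Z. The measurements of interest are per-seed: how
many seeds the pod holds, where each sits, its size and shape, and which
of the pod's two longitudinal chambers (valves, separated by the
pseudoseptum membrane) it occupies. Manual dissection destroys the
spatial arrangement; the pipeline here extracts everything from the
volume.

## Seeds as star-convex polyhedra

A body is star-convex about a center if every boundary point is visible
from that center, so the body is exactly the set
`{c + t·u : 0 ≤ t ≤ r(u)}` for a radius function `r` on the unit sphere.
Sampling `r` along a fixed direction set turns a seed into a short
vector of radial distances — a representation that is compact, easy to
rasterize, and well suited to rounded or ovate seeds.

**Fibonacci rays.** The direction set is the golden-angle spherical
lattice: for `k = 0 … n−1`, `z_k = 1 − 2(k+0.5)/n` and azimuth
`θ_k = k·π(3−√5)`. It is approximately equal-area, so each ray carries
comparable information. With per-axis anisotropy factors
`(a_Z, a_Y, a_X)` (each ≥ 1, the longest axis exactly 1) every lattice
vector is divided component-wise by the factors and renormalised. Note
the direction of the effect: axes with larger factors are the axes along
which objects are *shorter*, and dividing shrinks those components, so
rays rotate *away* from the short axes — the image of an even spherical
sample under the ellipsoid map, i.e. even coverage of a representative
ellipsoid. The tests assert this direction (mean |X component| decreases
for factors with `a_X` largest).

**Distances.** `boundary_distances()` marches from the center along each
ray in steps of 0.5 voxel (far below the ≥ 20-voxel seed scale) until
the sampled voxel leaves the instance, then bisects the bracket five
times, i.e. localises the crossing to 1/64 voxel — comfortably inside
the half-voxel accuracy the voxelization itself supports.

**Rasterization.** A voxel at offset `u` from the center is inside iff
`|u| ≤ r(û)`, where `r(û)` interpolates the per-ray distances
barycentrically over the spherical triangulation given by the convex
hull of the ray directions. Interpolating the *radius* (rather than
taking the planar facet through the three boundary points) makes a
constant distance vector rasterize to an exact ball; the planar
alternative systematically undershoots curved bodies (about 6% volume
deficit for a radius-10 ball at 96 rays, versus under 1% for radial
interpolation). The all-zero distance vector rasterizes to exactly the
center voxel, by documented convention.

**Ray count.** `reconstruction_accuracy()` extracts distances from each
labelled instance (center = the interior voxel nearest the centroid,
since a concave instance's centroid may fall outside it), rasterizes,
and scores IoU against the original mask. On phantom seeds the suite
verifies mean IoU > 0.8 with as few as 32 rays and > 0.9 from 64 rays
up, with accuracy non-decreasing in ray count; 96 rays is the package
default. Whether anisotropy should warp the rays or rescale the volume
is not decidable from the representation itself; ray warping is
implemented, volume rescaling would be the equivalent alternative.

**Anisotropy estimate.** `empirical_anisotropy()` takes per-axis median
bounding-box extents over all instances and divides the largest median
by each axis's median, giving 1 on the longest axis. Median extents
`(32, 31, 29)` yield `(1, 1.032258…, 1.103448…)`, the regime typical of
slightly prolate seeds lying along Z.

## Training-free detection

The detector reproduces the candidate → suppression → label pipeline of
star-convex segmentation networks with deterministic classical stages,
so the geometry and evaluation machinery can be exercised end-to-end
without a trained model; externally produced label volumes can be
substituted at any time via `import_external_labels()` (labels renumbered
`1..k` by first appearance).

1. **Binarize** — a fixed threshold or volume-wide Otsu on a 256-bin
   histogram (implemented directly; installed alternatives are
   per-2D-slice).
2. **Candidates** — the exact squared Euclidean distance transform of
   the foreground (separable lower-envelope algorithm); every local
   maximum under 26-connectivity becomes a candidate center, with
   plateaus of equal value merged to the voxel nearest the plateau
   centroid (ties broken lexicographically). The candidate's score is
   its distance-transform value over the volume-wide maximum: deep
   interiors of seed-sized bodies score near 1, ridges of the thin pod
   wall score near the wall half-thickness over the largest seed radius
   (≈ 0.1), so a score threshold separates them cleanly.
3. **Score filter** then **NMS** — candidates are visited in descending
   score (ties by lexicographic center order); one is kept iff its
   rasterized-polyhedron IoU with every already-kept candidate is at
   most `nms_threshold`. Note the convention: *higher* thresholds prune
   *less*. The opposite reading ("higher = more aggressive") exists in
   the literature; this package documents and tests the
   suppress-when-overlap-exceeds convention.
4. **Labels** — survivors are rasterized and painted in descending
   score; overlapping voxels go to the higher-scoring instance;
   instances below `min_volume` voxels (default 500, about a third of
   the smallest phantom seed) are dropped and labels renumbered.

Defaults: `score_threshold = 0.3` (below the ≈ 0.38 worst-case score of
the smallest seed in the largest-seed volume, well above wall scores),
`nms_threshold = 0.4`, 96 rays. `optimize_thresholds()` replaces these
defaults with an exhaustive, fully deterministic grid search maximising
mean F1 over an IoU-threshold grid on validation volumes, with ties
broken toward the smaller NMS then smaller score threshold. The
evaluation τ and the detector's tunable confidence threshold are
deliberately given distinct names (`tau` vs `score_threshold`); reusing
one symbol for both is a standing source of confusion.

## Evaluation metrics

`match_instances()` computes the IoU matrix from the joint label
histogram and selects the one-to-one assignment maximising total IoU
among pairs with `IoU ≥ τ` (Hungarian assignment via `clue`). For
τ ≥ 0.5 at most one prediction can clear the threshold per ground-truth
instance — two disjoint predictions cannot both reach IoU 0.5 with the
same object — so greedy and optimal matching provably coincide there;
below 0.5 a deterministic optimal rule is required and enforced (the
suite checks it against exhaustive enumeration on up to 5×5 problems).
Zero-overlap pairs never match, whatever τ.

From `TP` matches among `n_true` and `n_pred` instances:
`recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`, `F1 = 2PR/(P+R)`,
`mean matched score` = mean matched IoU, `mean true score` = summed
matched IoU over `n_true`, and `panoptic quality` = summed matched IoU
over `TP + FP/2 + FN/2`. Every 0/0 is defined as 0; these conventions
only touch degenerate empty cases. The identities
`TP + FN = n_true`, `TP + FP = n_pred`,
`PQ = mean_matched · TP/(TP+FP/2+FN/2)` and
`mean_true = mean_matched · TP/n_true` hold exactly by construction, and
the mean matched score is computed per-τ from that τ's own matches.

## Shape measurement

Coordinates are 0-based and bounding boxes half-open `[min, max)`, so
per-axis `max − min` multiplies to the bounding-box volume — the
convention that keeps the location and shape blocks of the CSV report
mutually consistent. Per instance: volume = voxel count;
`extent = volume / bbox_volume`; convex volume = voxels whose centers
lie inside the convex hull of the instance's boundary-voxel centers
(hull built by an exact incremental algorithm; voxels on the hull
surface are included; degenerate flat instances fall back to
`convex_volume = volume`); `solidity = volume / convex_volume`.

`equivalent_diameter = (6V/π)^(1/3)`, the sphere — not circle — with the
instance's volume: the 3D formula is what makes the reported diameters
consistent with the reported volumes (e.g. volume 23237 gives 35.405).

Surface area is the total triangle area of the 0.5-level isosurface of
the binary instance, padded and pre-smoothed with the 7-point
face-neighbour kernel, extracted by marching tetrahedra (six tetrahedra
per grid cube; per-tetrahedron case analysis is exhaustive and trivially
verifiable, unlike the 256-entry cube table, and the algorithm is fixed
and deterministic). The smoothing matters: raw-binary isosurfaces
overestimate the area of curved bodies enough to push a voxelized
radius-15 ball's sphericity (`π^(1/3)(6V)^(2/3)/A`) below 0.92, while
the smoothed mesh keeps it above 0.95, the regime expected for
near-spherical seeds; a 21-voxel cube lands within 5% of the closed-form
`(π/6)^(1/3) ≈ 0.806`. Instances too small for the smoothed field to
cross the level (a few voxels) are meshed on the raw binary instead.

Major/minor axis lengths use the solid-ellipsoid moment relation: the
eigenvalues λ of the voxel-coordinate covariance give `2√(5λ)` for the
ellipsoid with the same second central moments. Printed axis lengths of
real pipelines are orientation- and convention-dependent, so the suite
property-tests this convention (ordering, exact recovery on voxelized
ellipsoids to 5%) rather than anchoring it to any external number.

## Valve sorting

In the `(Z, X)` cross-section the pseudoseptum is a smooth curve: Z
spans hundreds of slices along the pod while X centroids vary by a few
tens of voxels across the two valves, so the regression must be of X on
Z. A lowess fit (`stats::lowess`, Cleveland's algorithm, `delta = 0`,
3 robustifying iterations) through the seed centroids reconstructs the
curve; the sign of a seed's X-residual assigns valve 1 (above) or
valve 2 (below), residual exactly 0 going to valve 1 as the documented
deterministic tie-break. The smoother span is `f = 1` for pods with
≤ 5 seeds (too few points to support a local fit) and the lowess default
`f = 2/3` otherwise, both overridable. Within each valve seeds are
sequenced by ascending Z (beak to pedicel) and spacing is the Euclidean
distance between consecutive same-valve centroids in the `(Z, X)` plane
(the planar rather than 3D distance: the quantity describes positions
along the valve, and Y jitter is noise at this scale). Which physical
side is "valve 1" depends only on scan orientation, so
`valve_accuracy()` maximises over the two label permutations.

The test suite cross-checks the lowess path against an independent
direct reimplementation of Cleveland's local fits to 1e-8 on up to 30
points. That comparison is made on data whose residuals are far from
machine epsilon: when a fit interpolates its points exactly, the
robustness weights divide rounding noise by rounding noise and no two
implementations can agree bit-for-bit — a numerical regime, not an
algorithmic disagreement.

## The pod phantom

`generate_pod()` emulates the structure the pipeline depends on: a pod
wall shell (elliptical tube along Z), two rows of seeds alternating
(with occasional same-side "flips", probability 0.1) across a smooth
random cubic pseudoseptum curve, per-seed star-convex bodies — a base
ellipsoid radius times `1 + p(û)` with `p` a 4-term directional
polynomial series of amplitude ≤ 0.15, which keeps every body
star-convex by construction — composited as seed > wall > background
intensities `(0.85, 0.45, 0.1)` with additive Gaussian noise
(SD 0.05, i.e. seed–background SNR 15, clipped to `[0, 1]`), and exact
labels plus valve/sequence truth. Non-overlap is enforced by rejection
sampling (pairwise center distance greater than the sum of maximal radii
plus a 3-voxel clearance, bounded retries). Base radii are 10–18 voxels
with per-axis scales in `[0.85, 1]`, giving extents near 20–36 voxels —
the seed scale of real µCT pods — while the default volume is
256×128×128 rather than full scan size (up to 1397×512×512), keeping the
end-to-end suite fast; the Z extent grows automatically with the seed
count in `generate_study()`. The reconstruction and valve acceptance
studies use 50 standalone seeds and 30 pods of 7–10 seeds respectively.

What the phantom deliberately does **not** emulate: beam hardening, ring
artifacts and other CT physics (plain additive noise suffices for a
threshold/distance-transform detector); beak and pedicel structures;
seeds touching each other or the wall; partially filled or aborted
seeds. Consequently, passing tests demonstrate the correctness of the
geometry, matching, measurement and sorting machinery under realistic
scale and noise — not detector robustness to densely packed or
degenerate real-world pods, where a learned detector and the
`import_external_labels()` path are the intended route.

## Numerical conventions and degenerate inputs

* IoU of two empty masks is 0; 0/0 metric ratios are 0.
* March step 0.5 voxel with 5 bisections; rasterization tolerance 1e-9
  on the barycentric tests, with a best-facet fallback for directions on
  triangulation seams.
* All RNG-consuming functions take an explicit seed and run on a private
  RNG stream, restoring the caller's state; per-pod seeds in a study are
  derived from the master seed.
* Label volumes store 16-bit integers in TIFF (labels ≤ 65535); images
  store 32-bit float in `[0, 1]` — float TIFF storage outside that range
  is undefined in the underlying library, so intensities are kept
  normalised throughout.
* Ties: NMS visiting order breaks score ties lexicographically by
  center; plateau representatives break distance ties lexicographically;
  the assignment solver is deterministic for fixed input; valve residual
  0 goes to valve 1.

## Known limitations

* The classical detector assumes seeds are brighter than wall and
  background and separated by at least a few voxels; merged or touching
  seeds would need the external-model path.
* Surface area (hence sphericity) carries the usual isosurface
  discretisation bias for small instances (under ~10 voxels diameter).
* 32-bit integer TIFF labels are not supported by the reader (8/16-bit
  integer and 32-bit float are); label counts in practice are far below
  the 16-bit limit.
* Physical-unit calibration (µm per voxel) is carried as metadata only;
  all reported quantities are in voxel units.
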