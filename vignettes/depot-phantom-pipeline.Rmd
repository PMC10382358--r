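---
title: "Quantifying large-volume subcutaneous depots from axial MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying large-volume subcutaneous depots from axial MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large-volume subcutaneous (LVSC) injections — cumulative saline boluses of
2–10 mL delivered into the hypodermis of the abdomen, thigh or upper arm —
form a localized fluid depot between two tissue interfaces: the
intradermal/subcutaneous (ID/SC) boundary above and the
subcutaneous/intramuscular (SC/IM, muscle fascia) boundary below. On a
T2-weighted fast-spin-echo sequence the free fluid of the depot is brighter
than the surrounding subcutaneous fat, the fat brighter than muscle, and the
dermis essentially invisible. `depotmri` implements the complete quantitative
chain from a stack of axial slices to depot morphometrics: depot segmentation
from the grayscale histogram, extraction of both tissue boundaries as height
fields, correction of four characteristic artifacts, rigid alignment of the
scans of one injection series, and the geometric measurements — depot volume,
depth, projected area and principal axes, subcutaneous thickness maps, and
the thickness tracked at a fixed reference point across the injection
sequence.

Because the clinical scans the method was developed on are not publicly
available, the package ships a synthetic phantom generator with exact ground
truth. All validation in the test suite runs against this phantom.

## The phantom

`phantom_spec()` describes one injection site; `generate_series()` renders
one volume per acquisition stage — `naive` (pre-cannulation), `insertion`
(cannula placed), one stage per cumulative volume (`v2`, `v5`, `v10`;
the arm protocol stops at 5 mL), and `post_removal` — plus complete ground
truth.

**Acquisition geometry.** 0.6 mm in-plane resolution, 4 mm slice pitch
(3 mm slab + 1 mm skip) and a 10.8 cm stack, i.e. 27 axial slices. Each
voxel value is the average of a 5 × 3 grid of sub-samples across the voxel
depth extent and the central 3 mm of the slab, giving the partial-volume
ramps at tissue interfaces that real voxels have; the 1 mm inter-slab skip
is represented by not sampling it. The in-plane field of view is not fixed
by the protocol and is a site parameter (abdomen 160 mm, thigh 120 mm,
arm 100 mm laterally); the abdomen needs the largest lateral extent because
its small relative SC expansion must still accommodate a 10 mL bolus (see
*Conservation* below).

**Anatomy.** The SC/IM interface is a shallow bowl: zero slope at the
cannula position, receding by up to ~2 mm toward the edges. The baseline SC
thickness field peaks at the cannula position with a gentle (±0.8 mm)
large-wavelength modulation. The dermis (1.8 mm by default) is rendered at
background intensity — invisible, exactly as in the target sequence — and
four fish-oil fiducial capsules (4.5 mm oil radius, 0.5 mm wall) rest on the
skin, bracketing the site at ±28 mm lateral and ±22 mm along the stack.

**Injection response.** The muscle interface stays fixed across stages;
injection lifts the ID/SC interface (and skin) by a Gaussian bump. Two
constraints pin the bump exactly: its apex equals the requested per-stage
thickness increment at the cannula position, and its integral equals the
injected volume, so the SC-layer volume expands by exactly the bolus volume
(the tissue conforms). The bump width is solved from these two constraints
by root finding on the discrete grid. The depot itself is an oblate
lobulated blob (seeded low-order angular perturbations of an ellipsoid,
clipped to the SC layer) sitting 1.2 mm above the muscle interface; its
radial scale is solved by bisection so that the voxelised mask volume equals
the target volume to well under one voxel. If a requested volume cannot fit
between the boundaries — or the expansion cannot be accommodated within the
field of view — the generator raises an infeasible-geometry error rather
than silently distorting the anatomy.

**Study-condition presets.** `lvsc_study_spec(site, variant)` pins the
per-stage apex thicknesses to the per-site reference conditions in
`lvsc_site_reference()`. Site-level mean percent changes are means of
per-subject ratios, which is not the ratio of the site-mean thicknesses, so
no single phantom can reproduce both the absolute thickness means and the
mean percent changes at once. The two presets resolve this: `"absolute"`
pins the final stage to the site's reported absolute mean thickness,
`"ratio"` sets every stage to `baseline × (1 + pct/100)`.

**Artifacts** (`apply_artifacts()`), in application order:

1. *Breathing stair-step*: per-slice in-plane translations (default: an
   alternating ±1.5 mm depth-axis schedule for the abdomen, none elsewhere),
   applied by bilinear in-plane resampling.
2. *Metal-cannula void*: a cylinder of background intensity around the
   cannula axis (default radius 3 mm), from just above the skin to ~9 mm
   below the ID/SC interface, only while the cannula is in situ (`insertion`
   through the last injection, not `naive`/`post_removal`).
3. *Attenuation bias*: a multiplicative low-order field (default ±15%
   laterally with a mild depth interaction).
4. *Noise*: additive Gaussian (default σ = 4 against a fat level of 110),
   with a Rician option.

The `naive` and `post_removal` stages are rendered in a slightly
repositioned frame (seeded rigid offset, ±1.5 mm / ±1.5°, rotation about the
stack axis), mimicking subject removal and repositioning; the truth records
every transform, shift schedule, mask and surface.

**What the phantom does not emulate:** interstitial flow physics (the depot
shape is statistical, not mechanistic), k-space acquisition and its
artifacts (ghosting, chemical shift), intra-stage motion blur,
subject-to-subject anatomical variability beyond the site parameters, and
deformable (non-rigid) repositioning. Passing tests therefore demonstrate
that the pipeline recovers known geometry under realistic contrast, partial
volume, noise and the four modelled artifacts — not that it is robust to
every property of clinical data.

## The analysis chain

`process_series()` runs, per stage:

1. **Fiducial detection** (`detect_fiducials()`): bright connected
   components of capsule-like volume whose one-voxel shell is predominantly
   background (capsules float above the skin, separated by the invisible
   dermis). The oil's lower surface is estimated by a sphere fit across
   per-slice chord areas, which is robust to the slab averaging that erodes
   the bottom voxel layer.
2. **ROI extraction** (`extract_roi()`) around the fiducial centroid
   (±48 mm default), keeping physical coordinates.
3. **Attenuation correction** (`bias_correct()`): a polynomial (order 2
   default, 1–3 supported) fitted to the log intensities of the largest
   non-background tissue class, normalised to mean one and divided out. A
   constant image returns unchanged with a notice.
4. **Tissue classes** (`classify_tissue()`): k-means (k = 3, deterministic
   quantile initialisation) for background/muscle/fat plus a bright class
   above `fat + 0.5·(fat − muscle)`. Class *levels* are re-estimated as
   within-class medians: partial-volume mixtures drag k-means centers, and
   the sub-voxel boundary estimator needs unbiased levels.
5. **Boundary extraction** (`extract_boundaries()`): per column, the SC/IM
   boundary is the entry into the contiguous deep muscle block and the ID/SC
   boundary the first fat/bright voxel above it not separated by a
   background gap ≥ 1.2 mm (which excludes the floating capsules above the
   dermis gap; partial-volume voxels in the muscle intensity band count as
   gap above the muscle block). Sub-voxel depths come from the
   partial-volume fraction of the single mixed voxel at each interface —
   exact for box-averaged voxels and robust to a second interface one voxel
   away (the depot sits just under the ID/SC boundary). Columns are then
   cleaned by a lateral outlier rejection (21-column running median,
   2 mm gate), a lateral median and light mean filter — all strictly within
   slice, so per-slice structure (the stair-step) survives for the
   realignment step — and invalid columns are bridged from neighbours.
   Columns touched by the cannula void carry no ID/SC signal and are
   re-extracted as invalid in a second pass.
6. **Slice realignment** (`realign_slices()`): per slice, the in-plane
   translation minimising the squared contour mismatch against the
   neighbouring slices' average, with a median offset estimator (a few
   void-corrupted columns must not masquerade as a slice shift), damped
   fixed-point iteration, and a zero-net-shift constraint. The correction is
   applied to the volume only when the estimated schedule exceeds 0.4 mm
   RMS: genuine breathing is ~1.5 mm, while smooth anatomical z-variation
   produces sub-0.4 mm pseudo-shifts.
7. **Threshold and segmentation** (`select_threshold()`,
   `segment_depot()`): Otsu's threshold (default; valley and fixed methods
   available) on the histogram of the SC band near the injection site —
   restricting to the SC layer keeps air and muscle from dominating the
   histogram, and to the site neighbourhood so the depot carries
   non-negligible mass. The mask is cleaned by an in-plane opening (0.6 mm),
   labelled in 3-D (26-neighbourhood), and the component intersecting a
   10 mm cylinder around the cannula axis wins (largest on ties). A closed
   voxel-face mesh is built whose enclosed volume equals the mask volume
   exactly.
8. **Alignment and backfill**: every stage is rigidly aligned to the
   post-removal scan by orthogonal Procrustes on the fiducial centroids,
   refined by a depth-offset fit against the SC/IM surface — the muscle
   interface does not deform with injection, whereas fiducials ride the
   expanding skin, so this choice keeps the anatomical expansion out of the
   rigid fit (an ICP refinement on surface samples is also available).
   Cannula-void voxels then adopt the aligned post-removal segmentation's
   occupancy (`backfill_void()`); no voxel outside the void changes.

Series-level measurements: `depot_volume()` (voxel count × voxel volume),
`min_distance()` (exact point-to-triangle minimum from depot vertices to a
boundary sheet, zero if crossing), `depth_from_skin()` (ID/SC distance plus
the dermal estimate from `estimate_dermal_thickness()`, i.e. fiducial gap
minus capsule wall, default 0.5 mm), `project_and_axes()` (orthographic
footprint on the fitted skin plane; area by triangle rasterisation at
0.3 mm, first principal axis as the maximal caliper width of the footprint
hull, second as the orthogonal extent), `thickness_map()` (per column the
minimum 3-D distance from the SC/IM point to the ID/SC sheet over a local
window — never larger than the vertical gap), and
`track_reference_thickness()`.

**The reference point.** The SC/IM surface point closest to the depot at the
largest-volume stage (exact point-to-triangle distances; slab-corner vertex
distances alone would be biased by up to half a pitch) is mapped through the
per-stage rigid transforms, and each stage's thickness is the minimum 3-D
distance from that fixed point to the stage's ID/SC sheet. Its depth is
de-noised by a local median, because an argmin over thousands of columns
systematically prefers shallow extraction noise. Percent change is reported
against the cannula-placement (insertion) scan; the pre-cannulation and
post-removal scans carry absolute values only, since the cannula pad
compresses tissue differently in those scans.

## Numerical choices and degenerate inputs

* All geometry in mm; volumes in mL (1 mL = 1000 mm³); voxel `(i, j, k)`
  centred at `origin + (c(i,j,k) − 0.5)·spacing`; axial slices along the
  third axis; boundary surfaces are depth fields over the (lateral, slice)
  grid.
* Otsu's threshold is placed halfway between the optimal split bin and the
  next; the valley method errors on a unimodal histogram ("no depot
  present"); a constant image makes class estimation fail loudly.
* Connected components: 26-neighbourhood (slice-wise labelling merged
  across all nine in-plane offsets by union-find). Morphology elements are
  specified in mm and converted per axis; at 4 mm pitch the opening is
  in-plane only.
* Ties when several components touch the cannula cylinder: the largest
  wins. An empty segmentation is a warning plus an empty mask (so the naive
  stage works as a negative control), not an error.
* Rigid fits need ≥ 3 non-collinear fiducials; capsules are matched across
  scans by angular order around their centroid.
* Depot meshes are closed voxel-face meshes — mesh volume ≡ mask volume, so
  the meshing step can never drift from the voxel count it reports.
* Determinism: every stochastic element (lobular shape, repositioning,
  noise) derives from the single spec seed; processing itself is free of
  random calls (k-means is initialised from quantiles), so a fixed seed
  reproduces every output byte-for-byte.

## Problem sizes and performance

The study-condition phantoms are 77–107 × 167–267 × 27 voxels per stage
(site-dependent), five or six stages per series. One full series generates
in ~10 s and processes in ~1–3 min on a single core; the test suite keeps
one reduced phantom (72 × 46 × 64 mm field of view, 2 + 5 mL stages) for
unit tests and generates each full-size series once per session for the
study-condition checks.

## Known limitations

* The reference-point measurement inherits the boundary extraction's
  accuracy (~0.1–0.2 mm on the phantom at default noise); percent changes
  compound the errors of two stages.
* The rigid alignment model is translation + rotation only; real
  repositioning includes tissue deformation that the depth-offset fit can
  only average over.
* The valley threshold method needs a genuinely bimodal histogram; at 2 mL
  in a large SC band the depot mass is small, which is why the pipeline
  restricts the histogram to the injection-site neighbourhood.
* The backfill transfers occupancy from the post-removal scan; if the depot
  redistributes after cannula removal, the filled core inherits that
  redistribution — matching the source method's assumption, not resolving
  it.
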