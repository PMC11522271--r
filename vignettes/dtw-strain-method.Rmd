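---
title: "Tracking-free LV strain from segmentation masks: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking-free LV strain from segmentation masks: method and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwstrain)
```

## The problem

Left-ventricular global longitudinal strain (LVGLS) is conventionally
measured by speckle tracking, which follows ultrasound texture patches
between frames. Tracking is vendor-specific, drifts over long clips, and is
unavailable for many data sources (point-of-care ultrasound, CMR cines,
videos without DICOM). Frame-by-frame *segmentation* of the LV myocardium,
in contrast, is modality- and vendor-agnostic. `dtwstrain` turns a
temporally ordered sequence of binary myocardial masks (apical
four-chamber or equivalent long-axis view) into global and regional
longitudinal strain without tracking anything between frames: every frame
is registered independently through its own geometry.

## The pipeline

Each frame passes through the same stages:

1. **Boundary and key points.** The largest foreground component is kept,
   holes are filled, and the boundary is traced as one closed polygon along
   the 0.5-level of the binary image, so its shoelace area matches the
   pixel count to within a fraction of a percent. The mask is thinned to a
   one-pixel skeleton (Zhang–Suen); on the convex hull of the skeleton, the
   adjacent vertex pair whose chord midpoint falls *outside* the foreground
   spans the open base of the U-shaped band — these are the septal and
   lateral mitral-annular endpoints. The apex is the boundary point with
   maximal coordinate along the major axis of a direct least-squares
   ellipse fit to the boundary, signed to point away from the annular
   midpoint.

2. **Layers and resampling.** Removing the two base end-caps (boundary
   points lying baseward of their annular endpoint) splits the boundary
   into two arcs; the one nearer the cavity centroid is the endocardium.
   Each arc is resampled to 193 points at equal arc-length steps per wall,
   with point 97 pinned to the apex projection: 96 intervals per wall plus
   the shared apex sample.

3. **DTW registration into blocks.** Dynamic time warping (Euclidean local
   cost, steps (1,0), (0,1), (1,1), both ends pinned, diagonal preferred on
   ties) pairs the 97 endocardial with the 97 epicardial points of each
   wall separately. Consecutive path nodes span small triangular or
   quadrilateral units. At the end-diastolic frame (largest cavity area)
   each wall's units are merged into 3 segments × 10 blocks at the nominal
   cumulative-area fractions k/30, snapped to the nearest unit boundary;
   the *achieved* post-snap fractions are recorded. In every other frame
   the borders are re-snapped to those recorded fractions — proportional
   area conservation: each block keeps its ED share of wall area even as
   the wall thickens and shortens. With both walls this yields 60 serially
   numbered blocks and 61 transversal borders per frame.

4. **Centerline and strain.** The midpoints of the 61 borders form the
   centerline; its length is the frame's myocardial length L. With the
   end-diastolic length L0, Lagrangian strain is (L − L0)/L0, negative
   during systole; the peak is the maximal absolute value. End-diastole is
   re-detected per cardiac cycle from the cavity-area series, and strain is
   re-zeroed at each cycle's own ED, so multi-beat clips need no drift
   correction — there is nothing to drift.

### Why per-wall DTW

Aligning each wall separately (97 vs 97, ends pinned) rather than the full
193-point layers guarantees that a border exists exactly at the apex and
lets the area-share constraint act on each wall independently. That matters
because the septum is usually thicker than the lateral wall: a single
global area budget would let basal septal blocks absorb lateral area.

### Segment boundaries are interpolated, blocks are not

Block borders snap to DTW path nodes, so a border can jump by one whole
unit between frames when the nearest node changes. Over the full
centerline these jumps average out, but a 10-block segment is short enough
that a one-unit jump at either end moves its length by ~1–2 % — pure
quantization noise that the per-segment peak (a maximum over frames)
rectifies into a bias. Segment *lengths* are therefore measured between
boundaries interpolated along the centerline at the exact ED
cumulative-fraction targets, while the blocks themselves (and the serial
numbers the hopscotch metric uses) remain merged runs of whole units. At
the ED frame the two coincide by construction.

## The hopscotch consistency metric

Externally tracked points (e.g. mid-myocardial speckle-tracking output) can
be overlaid on the blocks: each point gets the serial number of the block
containing it (points on a shared border take the lower serial; points
outside every block take the nearest one and are flagged). The score is the
signed mean, over all points and all frames after the first, of the
difference from the first-frame serial. Zero means block registration and
the external tracker agree about which piece of myocardium is which; the
signed mean is reported (a near-zero value indicates no systematic slip)
with the absolute mean alongside.

## The synthetic phantom

There is no public reference dataset of segmented LV mask sequences with
known strain, so validation uses a phantom built to have *analytic* ground
truth. Its mid-curve is a half-ellipse from the septal annulus over the
apex to the lateral annulus — the simplest smooth U with a closed-form
parameterization. Frame τ scales the mid-curve by
λ(τ) = 1 − a·sin²(π·τ/T) about the base midpoint and scales local wall
thickness by 1/λ, so in-plane band area is conserved (the same no
out-of-plane-motion assumption the block registration relies on) and
ground-truth strain is exactly λ − 1, uniformly along the band: peak strain
is −a by construction, frame 1 is end-diastole, mid-cycle end-systole.
Rasterization marks a pixel foreground when its center lies within the
local half-thickness of the mid-curve, clipped at the annular plane so the
base ends are blunt and the cavity opens cleanly. Co-moving tracking points
keep a fixed arc-length fraction of the mid-curve — the material motion of
the uniform deformation — default placement at midpoint-rule fractions
(k − 0.5)/n so no point sits exactly on a band end.

Default geometry (256×256 px, base width 110 px, long axis 160 px, wall
thickness 16/12 px septal/lateral, 0.6 mm/px) corresponds to roughly a
9 cm ventricle with 7–10 mm walls and mild septal-lateral asymmetry.

```{r phantom-demo}
spec <- phantom_spec(image_size = c(128, 128), base_width = 56,
                     long_axis = 80, thickness_septal = 10,
                     thickness_lateral = 8, shortening = 0.15, n_frames = 8)
ph <- generate_phantom(spec)
res <- dtw_strain(ph$masks)
round(100 * range(res$curve$table$strain), 2)
```

What the phantom deliberately does **not** emulate: ultrasound speckle and
dropout, segmentation-model noise, translational and out-of-plane motion,
foreshortening, regionally heterogeneous contraction, valve-plane
curvature. Passing the phantom tests shows the geometric pipeline is
correct and self-consistent; it does not certify accuracy on clinical
masks, where segmentation quality dominates.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `points_per_layer` | 193 | resampled points per contour layer; odd, apex at the middle index; 96 intervals per wall |
| `segments_per_wall` × `blocks_per_segment` | 3 × 10 | block structure: 60 blocks, 61 borders per frame |
| `septal_side` | `"left"` | which image side the septum is displayed on |
| `spacing` | 1 mm/px | pixel size; metadata only — strain is a length ratio and is scale-free |
| `prominence_frac` | 0.05 | cavity-area prominence (fraction of range) for an ED candidate |
| `min_sep_frac` | 1/3 | minimum ED spacing as a fraction of the dominant cycle length |

## Numerical choices and degenerate inputs

* **Boundary at the 0.5-level.** Tracing through pixel centers would bias
  the enclosed area low by about half the perimeter; the half-level contour
  matches the unit-square pixel model.
* **Arc smoothing.** Rasterized boundaries are half-pixel staircases; a
  short endpoint-preserving moving average (window 7 ≈ 3 px) is applied to
  each arc before resampling. Without it, equal arc-length steps along the
  staircase produce ~5 % chord-spacing ripple; with it, spacing is uniform
  to ~0.3 %.
* **Endpoint refinement.** Thinning retracts and branches at blunt wall
  ends, so a raw skeleton-hull vertex can sit half a wall thickness from
  the wall-end center. After the hull-chord detection, each endpoint is
  refined to the centroid of the baseward-extreme foreground slab (1.5 px)
  on its side; the apex likewise to the centroid of the near-flat boundary
  crown within 0.75 px of maximal projection. Both refinements are
  sub-pixel-accurate on the phantom.
* **Ties.** DTW backtracking prefers the diagonal; equal cavity areas take
  the earliest frame as ED; points on a shared block border take the lower
  serial; border snapping resolves monotonically left to right.
* **Degenerate inputs.** Empty masks, convex blobs (no open base), cap
  removal yielding ≠ 2 arcs, zero-length arcs, collinear ellipse fits, and
  non-positive reference lengths raise classed errors
  (`dtwstrain_no_foreground`, `dtwstrain_keypoint_failure`,
  `dtwstrain_split_failure`, `dtwstrain_degenerate_arc`,
  `dtwstrain_partition_failure`, `dtwstrain_invalid_reference`) carrying
  the frame index.
* **ED detection at sequence ends.** The first frame may be an ED (clips
  conventionally start there), but a terminal area rise with no following
  systolic drop is treated as the truncated start of a next cycle, not an
  ED — an ED must be followed within the series by a drop of at least the
  prominence threshold.
* **Equal units cannot merge into exactly equal blocks.** 96 units per
  wall merge into 30 blocks as runs of 3 or 4 units; the guaranteed bound
  is that every achieved cumulative fraction is within one unit's area
  fraction of its target, and that bound is exposed per wall as
  `max_unit_fraction`.

## Problem sizes used in the test suite

Unit and property tests run on a 128-px, 16-frame phantom (and an 8-frame
static one); the validation suite uses the full 256-px, 32-frame
conditions for shortening amplitudes 5–30 %, a 192-px two-cycle sequence
for multi-beat behaviour, and 100 random wall pairs of length ≤ 8 for the
brute-force DTW oracle. These sizes keep the whole suite under a minute
per phantom while leaving rasterization error well below the tolerances
being tested.

## Known limitations

* The area-conservation premise fails under foreshortening, strong
  translation, or out-of-plane motion; the method inherits that assumption
  from the imaging, it cannot detect the violation.
* Only longitudinal strain from a single long-axis view is produced — no
  circumferential/radial strain, strain rate, or myocardial work.
* Accuracy on clinical data is bounded by segmentation quality; no
  temporal regularization is applied by default (each frame stands alone),
  so temporally incoherent masks propagate directly into the curve.
* Very irregular wall-thickness patterns (aneurysm, non-compaction) stress
  the endo–epi DTW pairing; the per-wall proportional-area constraint
  mitigates but does not remove this.
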