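---
title: "Methods: automated aortic quantification from binary segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated aortic quantification from binary segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`aortaquant` turns a binary segmentation of the thoracic aorta — produced by
any upstream segmentation model — into clinically interpretable geometry.
The chain is:

1. **Endpoint detection.** The mask is reduced to a unit-width curve
   skeleton by topology-preserving thinning; skeleton leaves, extended along
   their end tangents to the mask boundary, are the endpoint candidates.
   Candidates are ordered by descending world *z* (most superior first).
2. **Inlet/outlet selection.** When more than two candidates exist, the
   first candidate and the candidate farthest from it (Euclidean) are kept —
   the rule the automated workflow applies when the vascular topology offers
   more than two ends. Ties go to the earlier candidate.
3. **Centerline extraction.** A least-cost path through the 26-connected
   foreground, with each step costing its physical length times
   `1/(DT + 0.1 mm)` (`DT` = spacing-aware distance to background), runs
   along the medial axis. The voxel path is smoothed (5-point moving
   average), resampled to 1 mm arc steps, and refined by re-centering every
   sample on the centroid of its orthogonal cross-section.
4. **Straightening (curved planar reformation).** Rotation-minimizing
   frames (double-reflection transport) orient an orthogonal plane at every
   millimetre of arc length; the volume is resampled on those planes into a
   straightened volume with exactly 1 mm isotropic voxels.
5. **Cross-section profiles.** Per slice: area = pixel count of the largest
   4-connected component, and maximal (Feret) diameter = largest
   boundary-pixel-center distance via convex hull + rotating calipers. Both
   sequences are smoothed with a Savitzky–Golay filter (window 11, order 2).
6. **Segments, summaries, dilation.** Landmarks at the brachiocephalic
   trunk (`s_bct`) and left subclavian artery (`s_lsa`) origins partition
   arc length into ascending `[0, s_bct)`, arch `[s_bct, s_lsa]`, and
   descending `(s_lsa, end]`. Max/mean/median of the smoothed channels are
   reported per segment; a segment is flagged dilated when its max diameter
   strictly exceeds its threshold (defaults 40/35/30 mm for
   ascending/arch/descending).

Validation tooling ships alongside: overlap metrics (Dice, IoU),
surface-distance metrics (95% Hausdorff, average symmetric surface
distance), method-agreement statistics (Pearson with Fisher-z CI, ICC(2,1),
Bland–Altman), ROC analysis with bootstrap CIs and Youden operating points,
and a vascular phantom generator with exact analytic ground truth.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| centerline step | 1 | mm | working resolution of the straightened frame |
| cost regularizer eps | 0.1 | mm | guards `1/DT` near the boundary |
| path smoothing window | 5 | points | removes voxel staircase without shortcutting curves |
| plane extent | 80 | mm | > 2x the largest clinically plausible aortic diameter |
| Savitzky–Golay window / order | 11 / 2 | slices / degree | the smoothing applied to diameter and area sequences |
| dilation thresholds | 40 / 35 / 30 | mm | clinical cutoffs for ascending / arch / descending |
| endpoint truncation | one local radius (min 3) | slices | see below |

`run_quantify()` resamples anisotropic masks to 1 mm isotropic (nearest,
label-preserving) before any geometry: thick-slice (3 mm) masks otherwise
carry staircase terraces whose diagonal contacts corrupt skeleton topology.

## Numerical and design choices

**Thinning.** Sequential 6-direction subiteration thinning with an exact
simple-point test (one 26-component of foreground in N26, one 6-component
of face-connected background in N18). Curve tips are protected when they
have at most one neighbor, or exactly two mutually adjacent neighbors — a
digital staircase rod's tip is "simple" and plain homotopic thinning would
unravel it voxel by voxel; the one exception is a terminal 3-voxel triangle,
which must collapse so a clean leaf can form. Voxels peel in order of
increasing distance transform, so the surviving curve hugs the medial axis.

**Skeleton graph hygiene.** The voxel 26-adjacency graph of a digital curve
contains chord edges (corner triangles) that masquerade as junctions; a BFS
spanning tree drops them. Leaf branches whose every voxel lies inside the
inscribed sphere of some *other* skeleton voxel are pruned: such branches
run within the vessel they sprouted from (blunt-end and staircase
artifacts), whereas genuine side branches protrude beyond the inscribed
spheres and survive.

**Endpoint extension.** The medial axis of a blunt-ended tube legitimately
stops about one inscribed radius short of the end face. Each skeleton leaf
is therefore extended by a tube-tracking march: step 1 mm along the running
direction, re-center on the centroid of the orthogonal cross-section, steer
from a 5-step trailing baseline (per-step centroid jitter is the same order
as the step, so a one-step update would wander). The march stops when the
tracked axis point leaves the mask — which is precisely the end-face
center — with guards against grazing planes (centroid jumps larger than
3 steps, cross-section counts collapsing faster than any real taper).

**Endpoint truncation.** Reformation planes within about one inscribed
radius of an open end cut partial or oblique lumens. The truncation window
is therefore adaptive — one local end radius, estimated from the largest
cross-section among slices 2–10, never fewer than 3 slices — rather than a
fixed 3 slices, which under-flags wide vessels. A fixed window remains
available (`truncate_slices`).

**Savitzky–Golay.** Built from the normal equations of the windowed
polynomial fit, not delegated to a filter routine; any globally polynomial
sequence of degree ≤ order is reproduced exactly. Edges are *interpolating*:
the polynomial fitted to the terminal window is evaluated at the edge
positions, because truncation-style edge modes bias endpoint diameters —
exactly where the clinically interesting maxima can sit.

**Feret diameter.** Boundary-pixel centers (no half-pixel padding), convex
hull plus rotating calipers, exact ties with the brute-force pairwise
maximum. The pixel-center convention carries an up-to-one-pixel negative
bias that measurement tolerances absorb. Degenerate (collinear) hulls fall
back to the farthest hull-vertex pair.

**Surface distances.** Surfaces are boundary voxel centers under
6-connectivity (volume borders count as background). HD95 is the 95th
percentile (linear interpolation) of the pooled bidirectional
nearest-surface distance set; `pooled = FALSE` gives the
max-of-directed-percentiles alternative. Two empty masks compare as 1.0 for
overlap metrics; distance metrics refuse empty masks.

**ICC.** Fixed to ICC(2,1) — two-way random effects, absolute agreement,
single measurement — because the package's use case is method comparison
(reference vs automated measurement of the same subjects), where a fixed
bias must lower agreement; the F-based McGraw–Wong interval provides the
CI. **AUC** uses the Mann–Whitney midrank statistic (equal to the
trapezoidal area under the threshold-sweep curve) with a seeded percentile
bootstrap CI. "Optimal" sensitivity/specificity is the Youden-maximizing
operating point (ties: higher sensitivity, then lower threshold).

## The phantom generator: what it emulates, what it does not

Phantoms are voxelized by center-inclusion against exact analytic geometry,
so the ground truth (centerline, radius profile, landmark arc lengths,
per-segment max diameters) is exact and voxelization is the only error
source. The candy-cane shape — vertical ascending limb, half-torus arch,
vertical descending limb, optional outward stubs on the arch as
brachiocephalic/left-subclavian stand-ins — reproduces the thoracic aorta's
topology on an analytically known curve. Focal dilations are Gaussian
radius bumps (`s0`, amplitude, width = sigma, mm); bumps only ever increase
the true max diameter.

The paired cohort emulates the paired same-session validation design: the
"contrast" arm is the bare lumen at 0.65 mm in-plane / 1 mm slices, the
"non-contrast" arm is the lumen plus a 2 mm wall at 0.65 mm / 3 mm slices —
non-contrast segmentations cannot separate wall from lumen, which biases
diameters up by twice the wall thickness. The wall arm is voxelized as the
exact Euclidean dilation of the lumen (ball envelope, including axial
extension at the free ends), so the non-contrast mask provably contains the
contrast mask after resampling to a common grid. Cohort base radii default
to U(9.5, 12.5) mm so that no undilated segment sits within 5 mm of any
threshold, and dilated cases carry an ascending bulge lifting the true max
diameter at least 5 mm above the 40 mm threshold: dilated and undilated
cases are separable *by construction*, which is what makes the end-to-end
AUC = 1.0 acceptance check meaningful.

What the phantoms do **not** emulate: CT intensities and noise,
partial-volume effects at the segmentation stage, dissection lumens, motion
artifacts, anatomical variation of branch origins, or segmentation errors
of any real upstream model. A green phantom suite establishes that the
*geometry pipeline* measures correctly — it says nothing about segmentation
quality on real scans.

Known limitations: branch stubs shorter than roughly their own radius plus
the thinning retraction (about half the main-tube radius) are absorbed into
the medial axis and produce no endpoint candidate — stub fixtures use
radius 7 mm / length 22 mm, comfortably above that bound. Under the
first/farthest rule with descending-z ordering, a stub tip on top of the
arch would be selected as inlet (it is the most superior leaf); the paired
cohort therefore omits stubs and supplies landmark arc lengths as inputs,
which the workflow accepts by design.

## Degenerate inputs and tie-breaks

Empty masks, multi-component masks, inlet = outlet, disconnected
inlet/outlet, even smoothing windows, non-positive spacings and landmark
orderings all fail fast with named errors. Equidistant outlet candidates
resolve to the earlier list position; equal Youden indices resolve to
higher sensitivity then lower threshold; a measurement exactly at a
dilation threshold is *not* flagged (strict inequality).

## Reproducibility

All randomness flows from explicit integer seeds (`phantom_spec(seed=)`,
`make_paired_cohort(seed=)`, `roc_auc(seed=)`, `run_config(seed=)`); the
RNG state of the calling session is preserved and restored. Identical seeds
reproduce cohort masks and serialized reports byte-identically, and every
written result carries a provenance block (package version, config hash).
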