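---
title: "Prior-guided seeded region growing for lung tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided seeded region growing for lung tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorgrow)
```

## The problem

Lung tumors in a 2-D CT slice appear as bright soft-tissue blobs inside
the dark lung parenchyma.  Classical seeded region growing segments
them well, but requires a user to click a seed point and pick a gray
tolerance.  `priorgrow` removes both interactions: it localizes a tumor
candidate from prior knowledge of clinically relevant tumor sizes,
derives the seed automatically, and sets and updates the tolerance from
the image itself.  An ensemble of seven seeds, each grown with its own
tolerance and vetted by growth-restriction checks, makes the result
robust to an unluckily placed or unluckily noisy single seed.

## The method

**Localization.**  The slice is contrast-stretched (percentile clip,
see below), binarized with Otsu's threshold (the gray level maximizing
between-class variance of the histogram), and all 8-connected
foreground components are extracted as contours with holes filled.
Each contour is measured physically via the pixel spacing: its area
$A$ (cm²) and its maximum size (maximum Feret diameter, the longest
caliper distance between two boundary points, cm).  A contour is an
admissible tumor candidate iff

* condition (a): 2 cm < maximum size ≤ 5 cm, and
* condition (b): 1 cm² < area ≤ 6.25π cm².

The size window comes from the TNM (8th edition) T1c–T2b cut-points;
6.25π cm² is the area of the 5 cm circle, and the 1 cm² floor discards
vessel-tree cross-sections, which are thin and small in area even when
their length would pass condition (a).  The surviving contour is the
target contour $D$; its first-moment centroid over the filled region,
$C = (\iint_D x\,dA / A,\ \iint_D y\,dA / A)$, rounded to the nearest
pixel, is the initial seed $p_1$.  (Whether those integrals run over
the filled region or the boundary curve is a genuinely open reading; we
use the filled region — the standard region centroid — because the
boundary-curve centroid of a concave shape drifts toward densely
sampled boundary arcs.)  If several contours survive, each is segmented
independently and the largest-area one is marked primary; if none
survives, segmentation stops with an explicit error and the user can
bypass localization with a manual seed.

**Seed expansion.**  Three dividing lines through $C$ at mutual 60°
angles split the filled region of $D$ into six angular sectors; each
sector's pixel centroid becomes one of $p_2 \dots p_7$.  Sector
membership uses half-open intervals $[\theta, \theta + 60°)$ measured
from the image-row axis, so the sectors tile the region exactly and the
construction is deterministic (the line orientation is configurable via
`sector_offset_deg`).  For a concave region a sector centroid can fall
outside the region; it is then replaced by the midpoint of the shortest
line from $C$ to the region boundary *within that sector* (for the rare
case where even that midpoint is outside, the nearest interior pixel is
used and the replacement is flagged).  We restrict the fallback's
boundary search to the offending sector — the alternative reading
(nearest point on the whole boundary) coincides with it whenever the
nearest boundary point lies in the sector, which is the common case.

**Growing.**  From each seed, breadth-first region growing on the
*original* intensities: the seed's gray value is stored as the base
value, and a neighboring pixel joins iff its intensity differs from the
base by at most the current tolerance; newly joined pixels are queued
and the process repeats until no new growth points appear.  The base
value stays fixed (not a running mean), so the grown mask is exactly
the connected component of the similarity predicate containing the
seed — which makes the result monotone in the tolerance and easy to
validate against a brute-force fixpoint flood fill.  Growth is
8-connected by default, matching the contour extraction.

**Tolerance and its update.**  $p_1$ grows with tolerance equal to 20%
of the *gray threshold* of the input image, which we read as
$0.2 \times (\max - \min)$ of its intensities.  (The alternative
readings — 20% of the maximum, or of the Otsu threshold — are exposed
via `roi_stat`, but the range reading is the default: it is the only
one invariant to intensity offsets, consistent with the method's claim
that no absolute calibration is needed.)  For each later seed $p_k$,
the tolerance is recomputed locally: a circle of radius $L$ is drawn
around the previous seed, where $L$ is the maximum distance from that
seed to its grown boundary plus a 6-pixel margin, and the new tolerance
is 20% of the intensity range inside the circle.  We chain the update
through $p_{k-1}$ (each seed's circle is centered on the previous
seed's result); centering every circle on $p_1$ instead is available as
`anchor_p1 = TRUE`.  The "6 units" margin is read as 6 pixels, the only
spatial unit in play at that step.

**Growth restrictions.**  Each grown region is vetted: with a
user-supplied predicted maximum tumor size, the region is credible iff
its maximum Feret diameter (cm) does not exceed the prediction; without
one, the longest distance $r$ from $C$ to the boundary of $D$ defines a
circle, and the region is credible iff its pixel area does not exceed
$\pi r^2$.  One discretization subtlety: distances are measured between
pixel *centers*, while areas count whole unit squares, so $r$ carries a
$+0.5$ px correction — without it a grown region exactly equal to a
filled disk $D$ would narrowly fail its own circumscribed circle.  An
abnormal region is discarded entirely (binary accept/reject, no
truncation).  The final segmentation is the pixelwise union of the
credible regions; if all seven are abnormal the run fails explicitly
rather than returning anything.

**Evaluation.**  Against a reference mask $x$ with prediction $y$:
Dice $= 2|x \cap y| / (|x| + |y|)$ and Jaccard distance
$= 1 - |x \cap y| / |x \cup y|$.  Two empty masks are an error, not a
perfect score.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold_frac` | 0.2 | fraction | tolerance as a share of the reference intensity range |
| `margin_px` | 6 | px | update-circle radius margin |
| `connectivity` | 8 | — | growth and component connectivity |
| `predicted_max_size_cm` | unset | cm | switches credibility to the predicted-size rule |
| size window | (2, 5] | cm | prior condition (a) |
| area window | (1, 6.25π] | cm² | prior condition (b) |
| `low/high_percentile` | 0.02 / 0.98 | fraction | contrast-stretch clip |
| `spacing_mm` | from DICOM | mm/px | converts pixels to physical units |

The contrast stretch is a percentile-based linear map (no formula is
prescribed for this step; percentile clipping is the standard robust
choice and its 98% ceiling saturates isolated bright spots that would
otherwise binarize into spurious candidates).  The stretch feeds *only*
localization; growing always sees the original intensities, so the
stretch cannot distort the segmented boundary.  Anisotropic DICOM
spacing is averaged with a warning; PNG/TIFF input requires an explicit
spacing because those formats carry none.

## Coordinates and conventions

All coordinates are 1-based `(row, col)` pairs, R's native matrix
convention; boundary polygons are closed rings of pixel coordinates.
Otsu's threshold is computed on a 256-bin histogram spanning the
observed intensity range (hence exactly shift-equivariant), ties broken
toward the smallest maximizing threshold, foreground strictly above the
threshold.  8-/16-bit PNG depth is inferred from the decoded values
(8-bit data are exact multiples of 1/255) since the PNG reader does not
expose it.  The DICOM reader handles uncompressed little-endian
single-frame monochrome files — the form CT slices take — and rejects
compressed syntaxes explicitly.

## Degenerate inputs

Constant images: contrast stretch returns the input with a warning;
Otsu errors (no histogram to split); the initial tolerance is 0 with a
warning.  A region smaller than 7 pixels yields a degenerate seed set
(p1 repeated, flagged).  A sector with no pixels or no boundary points
omits its seed with a flag.  An empty previous region makes the
threshold update fall back to the initial whole-image rule, flagged.  A
concave region whose centroid falls outside itself moves $p_1$ to the
nearest interior pixel, flagged — the out-of-region fallback is defined
only for $p_2 \dots p_7$, so this extension is the package's own.

## The phantom generator

`generate_phantom()` emulates the geometry of a 512×512 lung slice:
dark exterior, a soft-tissue body ellipse, two dark lung fields, one
tumor blob (disk, ellipse, or concave crescent) of controllable
physical diameter in the left lung, thin bright vessel-like polylines
(2 px wide, cross-section area below the 1 cm² floor) in the right
lung, and additive Gaussian noise, all deterministic in `rng_seed`.
Default intensities (tumor 200, body 120, lung 60, exterior 0) keep
tumor-vs-lung contrast well above the 20% tolerance; the body ellipse
is sized to fill most of the frame so that the stretched histogram's
Otsu split lands between lung and soft tissue, as it does in real CT.

What the phantom does *not* emulate: Hounsfield-unit physics, texture
and partial-volume effects, juxtapleural or vessel-attached tumors,
ground-glass opacity, or multiple slices.  Passing the phantom suite
therefore demonstrates that the algorithm is implemented correctly and
behaves as designed under its stated assumptions — not that it attains
any particular accuracy on clinical data, which requires expert-annotated
CT (e.g. LIDC-IDRI) outside this package's scope.

## Validation choices

The test suite validates each primitive against an independent
brute-force oracle: queue-based growth against a fixpoint flood fill on
random 32×32 images; Otsu against an exhaustive per-candidate argmax;
centroid, Feret diameter and sector geometry against pixel enumeration,
$O(n^2)$ pairwise distances and the analytic $2R/\pi$ sector-centroid
distance of a disk.  End-to-end behaviour is validated on noise-free
phantoms (Dice ≥ 0.98 demanded), a 20-phantom suite with diameters
2.2–4.8 cm and noise sd up to 10 gray levels (mean Dice ≥ 0.95, every
region credible, no growth beyond the restriction circle), out-of-window
phantoms (1.5 cm and 6 cm must fail localization), and bit-level
determinism of repeated runs.  These sizes keep the whole suite inside
a half minute on one CPU while exercising every code path; the same
quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

Single-slice 2-D only; one tumor assumed per slice (extra admissible
blobs are reported as secondary candidates); tumors outside (2, 5] cm
require a manual seed, by design of the prior; fixed 60° sector
geometry; the credibility circle assumes roughly star-convex tumors and
may accept a leaked region whose area happens to stay under $\pi r^2$.
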