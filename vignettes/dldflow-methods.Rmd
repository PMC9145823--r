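---
title: "dldflow methods: counting and classifying DLD separations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dldflow methods: counting and classifying DLD separations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dldflow)
```

## The measurement and its assumptions

Deterministic lateral displacement (DLD) sorts particles by size against a
critical diameter fixed by the pillar array's gap, row shift and period.
At the device outlet the sorted stream fans into parallel outlet channels;
which channels a particle population exits through — the outlet
distribution — is the experiment's readout, and at elevated Reynolds
numbers it also shifts with flow rate, which is why the separation mode
(zigzag, mixed, bumped) must be inferred from data rather than assumed
from geometry alone.

dldflow counts particles in outlet-region videos and classifies the mode.
The counting method rests on three assumptions, stated up front because
every later rule depends on them:

* **Flow is left to right** and a particle never reverses. In the outlet
  region the flow is channelized, so a particle holds an approximately
  constant image row while its column advances.
* **A real particle is never stationary**; anything static is background.
* **The operator matched frame rate to flow rate**, so a particle moves a
  resolvable distance (at least ~2 px, ideally more than its own
  diameter) between consecutive frames.

## Pipeline

### De-skew

All downstream geometry assumes horizontal channels. The skew estimate is
the mean angle-from-horizontal of line segments found by a deterministic
near-horizontal Hough detector run on a Canny edge map. `auto_rotate()`
estimates, rotates about the frame center, re-estimates, and stops when
the residual is within `tolerance` (default 0.5°, maximum 5 iterations;
the tolerance value is a package choice — only its existence is inherent
to the method). Two details matter numerically:

* Each iteration resamples the *original* frame at the cumulative angle,
  so interpolation blur does not accumulate.
* A damping rule guards oscillation: when the cumulative requested
  rotation exceeds twice the first estimate, the request is replaced by
  1.5× the first estimate. The trigger compares the *cumulative* request
  against the first estimate, and the substitution replaces rather than
  adds — the reading that keeps the correction bounded by 2× the initial
  evidence.
* After rotation the frame is cropped to the largest axis-aligned interior
  rectangle (closed form), because resampling fill pixels would otherwise
  create spurious edges.

### Observation window

Two templates mark the upper and lower ends of the outlet array. Both are
matched by FFT-based normalized cross-correlation (zero-variance patches
score 0; matches below `min_score = 0.5` are rejected as low-confidence).
The left bound is the mean of the two matched columns; the right bound
adds the mean template width. This is one reading of "averaging the
template locations" for *both* horizontal bounds — it implies templates
that span the array's width, which is how the synthetic generator builds
them. Vertical bounds are the outermost rows touched by detected line
segments between the horizontal bounds.

### Wall segmentation

Within the window, rows vote: each Canny edge pixel votes for its row,
and each Hough segment votes for every row it covers. The sorted vote
list is split into groups wherever adjacent distinct rows differ by more
than `gap_threshold` (default 3 rows — the walls of interest are many
rows apart, and a wall's own edge rows are at most `wall thickness + 1`
apart); each group's most-voted row is a wall, ties to the smaller row so
the result is order-independent. A row only contributes Canny votes when
its edge-pixel count exceeds 20% of the window width (`min_row_fill`),
which keeps sparse vertical structure (pillar ends, localization marks)
from bridging two wall groups into one. Channels are the intervals
between consecutive walls, numbered top to bottom; a centroid exactly on
an interior wall belongs to the upper channel.

### Particle detection and repeat suppression

The first frame is the background candidate: any blobs found in it are
patched by replacing each blob pixel with the mean of its row's non-blob
pixels (excluding the blob pixels from the mean — including them would
bias the patch toward the particle; a fully covered row falls back to the
global non-blob mean and is flagged). Patching is idempotent: re-running
it on its own output changes nothing.

Per frame pair, both frames are background-subtracted (negatives
clamped), the residuals differenced (negatives clamped again), and blobs
extracted from the difference. The nonzero support of the difference is
the *newly occupied* area of the later frame — which is why a particle
trailing exactly one frame behind another in the same column track is
invisible: the leader's previous footprint subtracts it away (see the
generator notes below).

Blob extraction sweeps thresholds 10–220 in steps of 10, labels
4-connected components (solid blobs make 4- vs 8-connectivity
immaterial), filters by area and circularity, and merges candidates
within `min_dist` px across levels; a blob must appear at
`min_repeatability = 2` or more levels. Circularity is
`4·pi·area / perimeter^2` with the perimeter measured as crack length
(count of pixel edges between blob and background). Under that measure a
digitized disk scores ≈ 0.47–0.57 and a 1-px-thin segment ≈ 0.5 or less,
so the default floor is 0.4; contour-arc-length perimeters would score
disks near 1 but degenerate for thin shapes. `blob_params_for_particle()`
derives the area window from the nominal particle diameter and the µm/px
scale (half to four times the projected disk area) and enables a 0.8 px
Gaussian pre-filter, which acts as a matched filter: it stabilizes the
centroids of partial footprints at the window edge and pushes sensor
noise below the sweep floor.

Repeat suppression compares each pair's centroids (rounded to 0.1 px,
duplicates collapsed) against the previous pair's:

* row differs from every previous row by more than `row_tolerance`
  (1 px, the magnification-specific value the protocol fixes; exposed in
  config for other scales) → **new**;
* row within tolerance of a previous centroid but position changed →
  **repeat**, suppressed: the same particle advected downstream;
* exact positional repeat → **new**, because a real particle cannot be
  stationary. `stationary_is_new = FALSE` selects the conservative
  alternative for recordings where static artifacts survive background
  subtraction.

When several previous rows are within tolerance the nearest row wins,
ties to the smaller column gap. Percentages in the run summary are taken
over assigned detections, so they always close to 100%; unassigned
detections (outside the wall span) are reported separately and the counts
always conserve.

## The mode classifiers

Each run contributes a 14-feature record: flow rate (mL/min), nominal
particle size (µm), and the 12 per-outlet *fractions* of the assigned
total. Fractions rather than raw counts make records comparable across
runs with different injected totals; they are also non-negative, which
complement naive Bayes requires. Three families are trained and compared
under stratified 5-fold cross-validation (folds preserve class
proportions to within one record; fold remainders go to the currently
smallest folds, so 66 records split 14/13/13/13/13):

* **CNB** (complement naive Bayes, alpha = 1, no weight normalization) on
  raw features — standardization would break non-negativity;
* **KNN** with k swept over 2–55 per split, keeping the smallest k that
  attains the split's maximum accuracy;
* **SVM-RBF** with cost 1 and kernel width 1/14 (both config-exposed).

KNN and SVM operate on standardized features (fitted on each split's
training part): with mixed units, raw Euclidean distance would be
dominated by whichever feature happens to have the largest scale. The
model that is persisted is refit on the *best-accuracy split's* training
data — deliberately mirroring the tool's protocol even though selecting
by test-fold accuracy is optimistic; all five split accuracies are stored
in the model and its JSON sidecar so that optimism stays visible. Split
ties resolve to the lowest index. `class::knn` breaks prediction-vote
ties randomly, so every knn call is wrapped in a deterministic
seed derived from the training seed; fixed seed in, identical model out.

## The synthetic fixtures

`generate_dld_video()` renders the study conditions the pipeline is
tested under: 12 channels between 13 dark horizontal walls (20 px pitch,
2 px thickness, intensities background 100 / wall 30 / particle 220 on
the 8-bit scale), anti-aliased disk particles of radius 5 px (a 10 px
apparent diameter matches 10–20 µm objects at the ~1.5 µm/px scale such
recordings are typically made at), advection 12 px/frame so consecutive
footprints do not overlap, Gaussian sensor noise clipped to [0, 255],
and a global skew applied last. Frame 1 is particle-free by default so
background patching can be exercised separately
(`first_frame_particles = TRUE` puts particles in it). Short vertical
tick marks above the top wall and below the bottom wall — outside every
particle path — give the array-wide templates distinctive corners so
normalized cross-correlation can localize columns.

Particle schedules respect the physics of pair differencing:

* particles whose transits overlap in time keep rows at least
  `min_row_sep = 3` px apart, so the 1 px repeat tolerance can never
  merge two real particles;
* particles whose entry frames differ by at most one — whose columns
  therefore coincide within a footprint at some point, advection being
  uniform — keep a full particle diameter of row separation. Same-frame
  entries would otherwise fuse into one connected component, and a
  one-frame lag puts the follower inside the leader's previous-position
  wake, which frame differencing subtracts to zero.

These constraints are what "countable" means for this method; real
recordings violating them (co-moving particle pairs closer than a
diameter) will undercount regardless of implementation. The generator
does **not** emulate pillar-array hydrodynamics, illumination gradients,
focus drift, motion blur, or particle-size polydispersity — passing tests
demonstrate correctness of the counting and classification logic under
the stated conditions, not robustness to every optical artifact of real
microscopy.

`generate_mode_dataset()` draws flow rates uniformly over 0.5–4.0 mL/min
(the operating range of high-throughput DLD experiments), assigns sizes
by class (10 µm → zigzag, 15 µm → mixed, 20 µm → bumped), and places
each class's outlet mass on its own four-outlet block (zigzag low,
mixed middle, bumped high) with Dirichlet-style within-block variation;
`noise_sd` spills mass across blocks, and at 0 the classes have disjoint
supports and are separable by construction — the regime in which all
three families are expected to reach 100% cross-validated accuracy.

## Numerical choices and degenerate inputs

* Canny thresholds default to the median rule (0.66/1.33 × median
  intensity) on the Sobel magnitude; hysteresis grows strong edges
  through 8-connected weak pixels to a fixpoint. The growth step matters:
  along an anti-aliased, slightly tilted line the per-row gradient
  periodically dips just below the high threshold where the edge crosses
  a row boundary, and without full growth those dips become segment
  breaks. Non-maximum suppression keeps both pixels of an exact-tie
  plateau for the same reason.
* The Hough detector scans angles ±8° in 0.25° steps, but segment angles
  are refined by least squares over the supporting pixels, so angular
  resolution is limited by pixel noise, not by the scan grid. Minimum
  segment length defaults to 25% of the image width, maximum in-segment
  column gap to 5 px, both config-exposed.
* 16-bit sources are linearly rescaled to [0, 255] at read time; all
  thresholds are defined on the 8-bit scale. Color converts by BT.601
  luma; converting an already-gray image is the identity.
* Degenerate inputs fail loudly and specifically: empty videos,
  inconsistent frame sizes, frames without line structure, windows with
  a single line row, fewer than two walls, classes smaller than the fold
  count, unlabeled test records, and malformed dataset rows each raise a
  typed error naming the stage.
* Zero-total summaries report all-zero counts with percentages guarded
  to 0; they are excluded (with a warning) from classifier datasets.

## Problem sizes

The test suite and the acceptance script run the full pipeline on twelve
videos of 50–200 particles (about 190–520 frames each at 271 × 256 px),
chosen to exercise the full concurrency range while keeping a complete
run in the single-digit minutes on one CPU; the classifier experiments
use the 66-record dataset size throughout. Unit tests use smaller
fixtures (tens of particles) built by the same generator.

## Known limitations

* Pair differencing cannot count a particle that is never the sole new
  occupant of its row neighborhood (the wake and fusion cases above).
* Counting accuracy degrades when particle SNR approaches the blob
  sweep's lowest threshold (intensity contrast below ~20 of 255).
* The horizontal-bounds rule assumes array-wide templates; corner-only
  templates would need the alternative one-template-per-side reading.
* The persisted model is selected on test folds (by protocol); treat its
  best-split accuracy as optimistic and consult all five stored split
  accuracies.
* Channel assignment is only as good as wall segmentation; the QC
  overlay written by `cmd_detect()` exists precisely so users can verify
  walls before trusting per-outlet distributions.
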