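---
title: "Counting thrips on sticky traps from overlapping tiled captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting thrips on sticky traps from overlapping tiled captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(trapscan)
library(dplyr)
```

## The problem

Yellow sticky traps are the standard census tool for thrips in orchards:
the card attracts flying insects, and the catch is counted to decide when
to intervene. Manual counting under a microscope is slow and demands
taxonomic skill, particularly when the question is not "how many thrips"
but "how many *Scirtothrips dorsalis*" — an invasive, roughly 1 mm pest —
versus other, less damaging thrips species.

A practical alternative photographs the trap with a smartphone and hands
the images to an object detector. Because a 1 mm insect needs high
magnification, a single photograph cannot cover a 250 × 150 mm card at
useful resolution. The card is instead imaged as a **lattice of 24
overlapping captures** (6 columns × 4 rows), each a 2992 × 2992 px view of
a 50 × 50 mm field. Each capture is further resized to 2912 px — the
nearest lower multiple of the 416 px detector input — and cut into a 7 × 7
grid of tiles. The price of full coverage with overlap is that **one
physical insect can appear in up to four captures and, within a capture,
be cut in two by a tile border**. Turning per-tile detections into a
per-trap count is therefore primarily a deduplication problem, and that
problem — not the detector — is what this package implements, alongside
the geometry, annotation handling, evaluation metrics, and a synthetic
scene generator that stands in for field data.

## The capture-grid coordinate model

`trap_spec()` fixes the physical geometry: card width and height, the
square footprint of one capture (50 mm), the capture resolution (2992 px,
so the pixel scale is 59.84 px/mm), and the pose counts per axis.
`build_capture_grid()` lays the poses out row-major, equally spaced
end-to-end: the first footprint is flush with the card's top-left corner
and the last with the bottom-right. Equal spacing is the only symmetric
completion consistent with a stated pose count and full coverage; with the
defaults it gives a 40 mm horizontal stride (10 mm ≈ 20 % overlap) and a
33.3 mm vertical stride (16.7 mm ≈ 33 % overlap). Overlaps are always
*derived* from the configured geometry rather than hard-coded, so
non-default cards and lattices remain consistent. The millimetre-to-pixel
scale is uniform and square; lens distortion near the capture edges is not
modelled — the overlap redundancy exists precisely so that every insect is
seen well inside at least one capture.

All boxes are `(x, y, w, h)` in pixels with a half-open extent, origin at
the card's top-left, x rightwards, y downwards. `tile_to_global()` and
`global_to_tile()` compose the three affine pieces (resize, tile origin,
pose origin) and are exact inverses; a property test drives 1,000 random
boxes around the loop at 1e-9 px tolerance.

```{r geometry}
grid <- build_capture_grid(trap_spec())
grid
neighbor_offset_px(grid, c(0, 0), c(1, 0))
```

## Synthetic scenes as the test bed

No public image set exists for this task, so the package generates its
own ground truth, with the statistical structure of a real census:

* **Counts.** The bundled 65-trap manual census (`manual_trap_counts()`)
  has per-trap SD counts from 1 to 196 with variance ≈ 1760 against a mean
  of 36.5 — far too dispersed for a Poisson model. Per-trap loads are
  therefore negative binomial, with method-of-moments defaults fitted once
  from the census (SD: mean 36.46, size 0.77; OT: mean 4.72, size 0.67).
* **Placement.** Centres are uniform on the card with a 2 mm minimum
  separation (rejection sampling, erroring after 10,000 failed attempts).
  Trap adhesive holds insects where they land; there is no evidence of
  spatial clustering strong enough to model on a 250 mm card, and uniform
  placement exercises every seam and corner case of the geometry.
* **Bodies.** Each insect is a filled ellipse: length normal around 1 mm
  (15 % CV, truncated at 40 % of the mean), a 3:1 length-to-width aspect
  typical of thrips, uniform orientation. At 59.84 px/mm a body spans
  roughly 60 px in a capture — large enough to be a plausible detection
  target, small relative to the 10 mm overlap, so no insect straddles a
  seam without being wholly visible in at least one capture.
* **Lighting.** Transmittance renders are high contrast (insect 40/255 on
  background 230/255); reflectance renders are low contrast (insect
  120/255) with Gaussian pixel noise (σ = 8/255). These mimic back-lit
  versus camera-side illumination of the card.

One RNG stream per seed is consumed in a documented order (counts, then
positions, then sizes and angles), so every scene is bit-for-bit
reproducible. What the generator deliberately does **not** model:
photorealistic texture, adhesive glare, debris, lens distortion, or insect
morphology beyond a bounding box. Tests passing on synthetic scenes
validate the *bookkeeping* — geometry, labels, merging, counting, metrics
— not any detector's ability to recognise a real thrips.

Ground-truth labels follow the annotation convention of the training
pipeline: an insect's box is projected into every overlapping capture and
tile, clipped at borders, and a clipped fragment is kept only when it
retains at least 20 % of the full box area. The threshold keeps "parts of
thrips" (which real annotators label) while discarding uninformative
slivers; because an insect centre always lies inside the card, the largest
fragment of any insect is at least 25 % of its box, so no insect ever
vanishes from the label set.

```{r scene}
scene <- sample_scene(scene_spec(seed = 7), trap_spec(), trap_id = "demo")
scene
truth <- scene_annotations(scene, build_capture_grid(trap_spec()))
nrow(truth) # labels exceed insects: seam insects are labelled in every view
```

## The stub detector

`stub_detect()` replaces the trained network with a controllable error
model: per-box miss probability, Gaussian centre/size jitter, class-flip
probability, Beta-distributed confidences, and Poisson false positives
per tile. Its purpose is parameter recovery: when the pipeline is fed
detections with *known* error rates, the evaluation module must measure
those rates back (recall `(1 - p_miss)(1 - p_classflip)`, off-diagonal
confusion fraction `p_classflip`) within Monte-Carlo error. The noiseless
configuration (`noiseless_detector()`) reproduces ground truth exactly at
confidence 1 and anchors the conservation and mAP = 1 identities.

## Duplicate suppression

The field rule for recognising the same insect in two neighbouring
captures is an edge-distance identity: with `b` the distance to the shared
edge's orthogonal axis and `a`, `c` the distances of the box to the left
edges of the two captures, the boxes depict one insect when `b(1) = b(2)`
and `a − d = c`, where `d` is the pixel offset between the camera poses.
That identity is exact only for identical, jitter-free boxes, so
`deduplicate()` generalises it: same-class boxes from distinct source
tiles are linked when **any** of the following holds, and linked groups
collapse transitively (connected components) to the single most confident
box:

1. global-frame IoU ≥ `dup_iou` (default 0.5) — the workhorse rule;
2. corners coincide within `geom_tol_px` (default 2 px) — the exact
   edge-distance identity, kept as a fast, jitter-tolerant special case
   (`is_same_insect()`);
3. the intersection covers ≥ `dup_iou` of the *smaller* box — needed when
   one view saw the insect whole and a neighbouring view only a clipped
   fragment: the fragment's IoU against the full box equals its area
   fraction and can fall below 0.5, while intersection-over-minimum is 1;
4. edge-adjacent fragments: two boxes from *the same* capture, in
   neighbouring tiles of the 7 × 7 split, abutting within `geom_tol_px`
   at the shared border with matching transverse extents — the signature
   of one insect cut in two by a tile border, since both halves of a box
   cut by a vertical line inherit identical vertical extents.

Rule 4 originally required only overlapping transverse extents plus a
plausible merged aspect ratio (1/3 to 3), but that version fails a
corner case: an insect clipped by a tile border *and* truncated on the
transverse axis produces a merged box with aspect beyond 3 (thrips bodies
are themselves 3:1), and the fragments were not merged — one insect
counted twice. Matching transverse extents is both stricter (two distinct
abutting insects almost never share them) and correct for every cut
geometry, and with it the conservation property holds exactly: for 100
seeded scenes, noiseless detection plus merging returns precisely the
scene's per-class counts.

One refinement follows from the distinction between *duplicates* (full
views of one insect from different captures, where keeping the most
confident box is right) and *fragments* (partial views cut apart by a tile
border, where every piece is wrong on its own): the kept box's geometry is
the union of its component's boxes from the kept box's own capture. An
insect cut into four by both tile axes in its only covering capture is
thereby reassembled to its full on-card box; keeping a single quarter
fragment would fail the IoU-0.5 match against ground truth even though
the *count* was correct. Ground-truth boxes themselves
(`scene_boxes()`) are clipped to the card, since an insect overhanging
the trap edge is only observable — and only rendered — on-card. With both
in place the noiseless identity is exact: merged counts equal scene
counts *and* mAP@0.5 = 1.

Ties in the "most confident" choice are broken by larger box area, then
row-major source-tile order, then input order, making output
deterministic. `deduplicate()` is idempotent, monotone in `dup_iou`
(raising the threshold never merges more), and is checked against an
independent brute-force oracle — an O(n²) pairwise predicate re-derived
in test code with components from igraph — on 1,000 random instances with
planted duplicate clusters.

Counting is then trivial (`count_classes()`), and `build_intensity_map()`
collapses the overlapping footprints to their seam-bisected Voronoi
rectangles — one display cell per camera pose — binning per-cell counts on
the four-level display scale (1–4, saturating at 4; red for SD, blue for
OT, blends when both classes share a cell).

```{r merge}
det <- stub_detect(truth, noiseless_detector())
res <- merge_and_count(det, build_capture_grid(trap_spec()))
res
glance(res)
```

```{r map, fig.height = 4}
autoplot(res$intensity)
```

## Evaluation

`bbox_iou()` implements intersection-over-union on half-open boxes;
degenerate boxes score 0 against everything. Matching
(`match_detections()`) is greedy in descending confidence, one-to-one,
argmax-IoU above the threshold, with confidence ties broken by input
order. Average precision integrates the all-points interpolated precision
envelope of the confidence sweep — the modern PASCAL VOC convention,
chosen because "area under the precision–recall curve" does not by itself
pick an interpolation, and the all-points form is the least biased of the
standard choices. AP for a class with no ground truth is *undefined*
(`NA`), distinct from 0, and `mean_ap()` averages the defined classes.

Confusion matrices are compiled from **class-agnostic** localisation
followed by class tallies of the matched pairs. This is the only reading
under which an actual-versus-predicted table has constant row sums across
models (each row sums to the number of localised boxes of that actual
class), which is how the bundled validation tables behave (2244 SD and
304 OT per lighting dataset). A misclassified insect lands off-diagonal;
unmatched predictions and truths are reported as attributes rather than
silently dropped. The bundled `validation_confusion()` and
`validation_map50()` tables let the arithmetic be re-derived: per-class
recalls of 97.1 %, 90.7 %, 87.5 %, 88.2 %, 94.1 %, 87.3 % and 93.7 %, and
reflectance macro averages of 91.0 % and 87.85 % (87.9 % at one-decimal
half-up rounding). Published per-class mAP@0.5 and confusion-derived
recall coincide for some model/dataset blocks and differ by up to two
points for others; both metrics are computed and reported side by side
rather than forced to agree, since their equality depends on the
operating point.

```{r eval}
ev <- evaluate_detections(res$merged, tidy(res) %>%
  select(x, y, w, h, class)) # noiseless: perfect by construction
glance(ev)
```

## Numerical choices and degenerate inputs

* Bilinear interpolation for the capture resize (via EBImage), applied
  *before* tile splitting; reassembling split tiles reproduces the resized
  capture bit-exactly.
* YOLO annotation serialisation is fixed at 6 decimals; a write/read
  round trip is the identity after the first rounding. Parse errors report
  the offending line number; coordinates outside [0, 1] are rejected.
* Dataset splitting permutes deterministically under a seed and sizes the
  validation/test parts as `floor(ratio * n)`, remainder to training.
  Splits are not stratified by trap; tiles from one trap may land in
  different partitions.
* Empty inputs are legal everywhere: empty scenes render blank captures,
  empty detection sets merge to zero counts, and an evaluation with no
  ground truth reports the no-ground-truth condition instead of an AP.
* `geom_tol_px` defaults to 2 px — generous against floating-point noise,
  far below the ~120 px minimum insect separation, so the exact-geometry
  fast path cannot bridge distinct insects.

## Problem sizes used by the test suite

The suite validates study-scale bookkeeping (65 traps × 24 captures × 49
tiles = 76,440) through the geometry tables rather than by rasterising
2992 px images 1,560 times; rasters are exercised at full capture size
once and otherwise on a reduced 2 × 2-pose, 416 px trap where pixel-level
assertions are cheap. Statistical recoveries use 3,000 sampled scenes for
the count distribution and 10,584 boxes for detector-rate recovery;
conservation runs 100 full scenes and the dedup oracle 1,000 random
instances of up to ~450 boxes.

## Known limitations

* The stub detector is not a vision model; nothing here certifies real
  detector accuracy on real traps. The bundled validation tables are
  fixed inputs for arithmetic checks, not reproducible measurements.
* The geometry model assumes an ideal lattice: no pose error, no lens
  distortion, square pixels. Real rigs drift; the overlap margins absorb
  small errors but the package does not estimate them.
* Duplicate suppression assumes duplicates coincide spatially after the
  global transform. A detector with gross localisation error (IoU < 0.5
  against its duplicate) under-merges; confidence-weighted box fusion is
  out of scope.
* The intensity map uses one display cell per camera pose; finer
  heat-mapping would need a different cell partition.
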