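---
title: "Methods: detector-agnostic nodulation phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector-agnostic nodulation phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulescan)
```

## The problem

Soybean root nodules are small (tens of pixels) objects scattered over
large plate images (≈2300 × 4600 px). Detectors work on fixed-size
inputs, so inference is run patch-wise over an overlapping grid and the
per-patch boxes must be reassembled into one clean set of full-image
detections before any biology can be read off them. `nodulescan`
implements that reassembly, the 24-trait extraction that follows it, the
evaluation protocol used to validate the detections, and the phenotype
statistics that prepare trait tables for association mapping. The
detector itself is deliberately out of scope: any backend that maps a
patch to boxes with confidences can drive the pipeline.

## Geometry conventions

All geometry uses continuous 0-based pixel coordinates with the origin
at the image top-left and y increasing downward; a box is the closed
rectangle `[x_min, x_max] × [y_min, y_max]` with strictly positive
extent, and its area is width × height. Working in continuous
coordinates avoids the ±1-pixel ambiguities of half-open pixel-grid
semantics; raster pixel `(row i, col j)` covers `[j-1, j] × [i-1, i]`.
Degenerate (zero-area) boxes are rejected everywhere — they have no
well-defined IoU. IoU is intersection area over union area; boxes that
share only an edge have IoU 0.

## Tiling and the containment guarantee

Patches are `patch_size` = 512 px squares whose origins step by
`stride = patch_size − overlap` = 448 px; the final origin on each axis
is clamped to `dim − patch_size` so the last patch ends exactly at the
image border. This keeps every patch full-size (as a fixed-input
detector expects), guarantees whole-image coverage, and avoids variable
strides everywhere except the final step. Images smaller than a patch
get one zero-padded patch. How the original grid met the image edge is
not observable from the published parameters; clamping is this
package's choice and is recorded as such.

The overlap of 64 px exceeds the largest nodule length in the reference
testing data (57 px), which yields the property the whole stitch-back
rests on: **any box with both sides ≤ overlap is fully contained,
unclipped, in at least one patch.** Annotations are remapped per patch
by translation and clipping, keeping any intersecting box — clipped
fragments train/evaluate patch detectors realistically, while the
containment guarantee ensures an unclipped copy exists somewhere.

## Stitch-back refinement

Patch-wise inference sees a nodule near a patch boundary several times.
Refinement restores one detection per nodule in two steps:

* **Edge filter (5 px).** A detection is removed iff any box side lies
  strictly within 5 px of a patch boundary, evaluated in the
  patch-local frame where "patch edge" is well defined. Such boxes are
  partially visible duplicates; the whole nodule survives in the
  neighboring patch. Boundaries that coincide with the outer image
  border are exempt by default (`exempt_image_border = TRUE`): a nodule
  touching the photo's edge exists only in a border patch, and
  filtering it there would lose it irrecoverably. The exemption can be
  switched off to mirror a uniform reading of the rule.
* **Greedy NMS (confidence 0.2, IoU 0.2).** After translation to
  full-image coordinates, all of an image's detections are pooled and
  suppressed greedily: sort by confidence descending (ties broken by
  `x_min`, then `y_min`, making output deterministic), keep the top
  box, remove everything overlapping it at IoU ≥ 0.2, repeat. The low
  confidence floor retains weak but valid detections; the low IoU
  threshold is appropriate because true nodules rarely overlap in 2D
  projection. Hard removal (not soft-NMS) is used, applied once,
  globally per image, after stitching.

Together with the containment guarantee this gives the oracle property
the tests exercise: perfect per-patch detections on scenes of separated
nodules come back *exactly* — one box per nodule, matching ground truth
at IoU ≥ 0.99. One caveat is worth stating precisely: the edge filter
narrows the per-patch safe window, so the unconditional guarantee holds
for boxes with sides ≤ overlap − 2 × edge_threshold = 54 px; a 55–57 px
nodule straddling two consecutive safe windows (a ≤3 px placement band
per 448 px of stride) could be filtered in both patches. Under the size
distribution below such sizes arise in ~0.2% of nodules, so the regime
the pipeline targets is unaffected; the limitation would matter only
for organs approaching the overlap width.

## Traits

From one image's final detections, 24 traits: `count`; `height` and
`width`, the vertical/horizontal span between extreme box *centers*;
`sdx` and `sdy`, the dispersions of center coordinates; their ratio
`sdxy = sdx / sdy` (directional asymmetry of nodulation); nine
statistics (min, max, sd, mean, median, 5th/25th/75th/95th percentiles)
over per-box areas; and the same nine over center y-coordinates, a
depth profile of nodulation along the root.

Numerical conventions, configurable but fixed by default:

* **Population SD** (`ddof = 0`) for every dispersion, matching the
  default of the mainstream array stack such pipelines are built on.
* **Percentiles** by linear interpolation between closest ranks
  (`quantile` type 7, the same default).
* **Degenerate inputs** never error: zero detections give `count = 0`
  and 23 missing values; one detection gives zero dispersions with
  `sdxy` missing (0/0); `sdy = 0` with `sdx > 0` gives a missing
  `sdxy` with a warning.

These choices make the traits translation-invariant (up to the
y-location statistics shifting by exactly the translation) and scale
covariant (lengths scale by *s*, areas by *s²*, `sdxy` and `count`
invariant), which the test suite verifies on random inputs against an
independent sort-and-interpolate oracle.

## Evaluation protocol

Predictions are matched to ground truth one-to-one and greedily by
descending IoU with threshold 0.5 (the de-facto standard; the matching
rule is not derivable from the published counts, so greedy matching is
this package's documented choice — on scenes whose candidate pairs are
disjoint it coincides with optimal assignment, which the tests verify
against an exhaustive oracle). Matched pairs are TP; unmatched
predictions FP; unmatched ground truth FN — so `tp + fn` is the
ground-truth count and `tp + fp` the prediction count by construction.

Zero-denominator conventions: an image with no ground truth and no
predictions scores P = R = F1 = 1; otherwise an undefined precision or
recall is 0. Images are stratified by labeled nodule count into bins
≤5, 6–10, 11–20, 21–30, ≥31 (the top bin closed upward so every count
is assigned); per-bin metrics are unweighted means of per-image values,
and the overall row is the unweighted mean of per-bin means — bins
count equally regardless of how many images they hold. Empty bins are
omitted from both the report and the overall average.

## Phenotype statistics

Trait tables across accessions are prepared for GWAS in three steps:
per-trait summaries (mean, population SD, CV% = 100·SD/mean);
**one-pass** Z-score outlier removal at |Z| ≥ 4, where Z is computed
from the unfiltered mean and SD and removal is cell-wise (the value
becomes missing; the accession's other traits are kept) — iterating to
convergence, or dropping whole accessions, would change results and is
not what a cell-wise reading implies; and pairwise-complete Pearson
correlations with a unit diagonal, reported only for pairs with ≥3
complete observations and non-zero variance. Zero-SD traits are never
filtered. The export layout (`Taxa` column + 24 traits, `NA` for
missing) is what rMVP/GAPIT-style tools consume.

## The synthetic generator and what it does (not) show

`generate_scene()` emulates the imaging setup: a blue-toned background,
a dark taproot stripe following a gentle sinusoidal curve, and sparse
elliptical nodules with tight ground-truth boxes, pairwise separated by
at least `min_separation` = 10 px (hence pairwise IoU 0). Nodule sizes
(the larger box side — "nodule length" is interpreted as the larger
side, which only the generator depends on) follow a lognormal with mean
19.93 px, truncated at 57 px. The lognormal's spread is calibrated so
the 57-px cap sits at its ~99.9th percentile (`sdlog ≈ 0.36`): a
reported *maximum over a testing set* of order 10³ nodules is naturally
an extreme quantile, not a typical value, and this is the one free
parameter of the size model. Layout can cluster nodules along the
taproot (`along_root_layout`) or scatter them uniformly; QR-like dot
decoys can be stamped on the background as negative controls for
raster detectors. Every scene is a pure function of its seed.

The mock detector corrupts ground truth with independent misses
(`fn_rate`), Gaussian center jitter (`jitter_sd`), uniform confidences,
and Poisson-count spurious boxes placed disjoint from all ground truth
— exactly the error structure the refinement and evaluation stages must
cope with, which makes the expected FN/FP rates recoverable and
testable.

What passing on synthetic scenes does **not** show: real plates have
touching and occluding nodules (pairwise IoU > 0), lateral-root debris,
lighting gradients, and detector confidence distributions unlike
uniform draws. The generator validates the *post-processing algebra* —
coordinate bookkeeping, duplicate collapse, trait formulas, protocol
arithmetic — not detector accuracy on real imagery.

## Problem sizes and determinism

The test suite runs full-geometry scenes (2300 × 4600 px, up to 72
nodules, 55 patches) for the end-to-end properties — geometry-only, no
rasterization, which is why they are cheap — and renders smaller scenes
(≈0.5 Mpx) where actual pixels are needed (blob detector, crop checks).
Error-rate recovery uses 200 simulated scenes of 20 nodules. All
randomized tests fix their seeds; `run_pipeline()` stamps outputs with
a config hash and seed, and reruns are byte-identical.

## Known limitations

* Strictly 2D: areas are projected box areas; occlusion biases sizes
  downward, and no depth information is represented.
* Single object class; rotated boxes and polygon masks are out of scope.
* The edge-filter caveat above for objects within 3 px of the overlap
  width.
* Greedy NMS and greedy matching are the documented tie-broken
  variants; other conventions (soft-NMS, Hungarian matching) would
  change counts in dense scenes.
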