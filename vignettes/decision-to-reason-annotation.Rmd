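---
title: "Decision-to-reason WSI annotation: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-to-reason WSI annotation: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsianno)
```

## The annotation model

`wsianno` models pathology annotations the way a diagnosing pathologist
works: a *decision* (slide- or region-level diagnosis) supported by
*reasons* (morphological findings). A document for one whole-slide image
(WSI) holds:

* **decision-layer regions** — polygons carrying a diagnostic class
  (adenocarcinoma, adenoma, normal) and optionally a finer subtype
  ("Poorly differentiated adenocarcinoma", "Tumor invasion", ...);
* **reason-layer regions** — polygons over individual features, tagged
  with reason labels from the terminology ("Cribriform structure",
  "Nuclei rod-shaped", ...) or free-text tokens;
* **bundles** — groups of regions sharing one caption, so the annotator
  describes many similar glands once;
* **phase metadata** — a quick *coarse* pass (class-level regions plus a
  slide-wise caption) and a *fine* pass (subtypes, reasons, bundles);
* optionally a reference to a **behavioral trace** of timestamped
  viewport events recorded while annotating.

The label vocabulary is a three-level forest (class → subtype → reason)
wrapped in `terminology_tree()`. The bundled colorectal fixture follows
the published structure of such a vocabulary — 3 classes, 12 subtypes and
77 reason labels (9 + 34 under adenocarcinoma, 2 + 25 under adenoma,
1 + 18 under normal) — using published term names where available and
clearly-flagged synthetic placeholders for the rest, since the full
clinical vocabulary is not publicly deposited. All count checks in the
package are data-driven; nothing assumes these constants.

Validation (`validate_annotation()`) enforces the structural invariants —
polygon sanity, label lineage (a subtype must be a child of its class, a
reason must descend from the region's subtype unless flagged free-text),
bundle membership, phase discipline — and reports machine-readable
violation codes rather than failing on the first problem.

### Design choices in the schema

* Region ids are caller-supplied and never renumbered: audits diff
  documents across time, and stable ids keep those diffs readable.
* A region carries at most one subtype; areas with two plausible
  diagnoses are modeled as overlapping regions, and the patch labeler
  resolves overlaps by severity.
* Free-text reason tokens (prefix `free:`) are carried through captions
  and BLEU scoring but are exempt from lineage validation.

## Interchange formats

Documents are versioned JSON, terminologies TSV, traces JSON Lines,
region geometry GeoJSON (RFC 7946 polygons, closed rings), patch
manifests CSV. The formats were chosen to be inspectable and diffable.
Two decisions worth noting:

* **Coordinates are integers.** Annotation pixels are discrete level-0
  positions; importers reject fractional coordinates instead of rounding
  silently.
* **Writers are deterministic** (stable key order, fixed float handling),
  so re-saving an unchanged document is byte-identical — a prerequisite
  for audit trails and for the end-to-end determinism tests.
* Axes follow raster convention: origin top-left, x right, y down,
  half-open pixel boxes.

## The patch pipeline

Slides are cut into square patches (default 256 px at the 20× level) on a
grid of half-open boxes, so with stride = patch size every pixel belongs
to exactly one patch. Plain PNG/TIFF rasters are first-class inputs,
which keeps the whole pipeline testable at desk scale.

* **Tissue masking.** Grayscale is smoothed (Gaussian, σ = 2 px) and
  thresholded by Otsu's criterion on a 256-bin histogram; tissue absorbs
  light, so foreground is the dark side. The threshold is the *smallest*
  maximizer of between-class variance, making ties deterministic. A
  patch is valid when its tissue fraction reaches 0.5 (configurable);
  blank images yield an empty mask rather than an error.
* **Stain normalization** uses the Macenko estimator: optical density
  `OD = -log10((I + 1)/I0)` with `I0 = 255`; pixels transparent in every
  channel (`OD < β = 0.15`) are discarded; the two stain directions are
  the α = 1 and 99 percentile angles within the plane of the top two
  singular vectors of the OD cloud; hematoxylin is the vector with the
  larger blue-channel absorbance; reference concentrations are the 99th
  percentile of the projections. These constants are the standard
  published defaults. Reconstruction keeps the raw least-squares
  concentrations (not clipped), which makes normalizing an image to its
  own model an exact identity; clipping is applied only where a physical
  non-negative concentration is needed (the reference maxima).
* **Labeling** follows the central-pixel rule: a patch inherits the label
  of the decision region containing its center, boundary counting as
  inside (favoring lesion recall). Overlapping regions resolve by
  severity priority (adenocarcinoma > adenoma > normal).
* **Splits and sampling.** Train/test splits are assigned per slide so no
  slide feeds both sets. Training patches are drawn uniformly without
  replacement per class to the requested targets, and normal-class
  patches come only from slides without any tumor region — tissue that
  merely *looks* normal on a tumor slide never enters the normal class.
  The generator supports labeling normal patches from explicit normal
  regions too, but the default follows the whole-normal-slide guarantee.
* **Test tiling** uses stride = patch size, emitting each foreground cell
  exactly once.

## Agreement metrics

Annotator consistency is scored at three levels, mirroring how audit
works in practice:

* **Slide level** — the slide classes of the two documents (the highest
  severity class present in each).
* **Patch level** — Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)` over
  central-pixel labels on a shared grid, computed separately for class
  and subtype labels. Patches unlabeled by *both* annotators are excluded
  by default: counting the shared background as agreement inflates κ on
  sparsely annotated slides (a flag restores it). When both raters are
  constant and identical, `p_e = 1`; this degenerate case is defined as
  κ = 1 and flagged.
* **Pixel level** — per-label Dice on regions rasterized at a 1/4 linear
  downsample (bounding memory; the rasterizer uses the same even-odd
  inside rule as patch labeling). Two empty masks score Dice 1, flagged.
* **Caption level** — BLEU-1 between captions of reason regions paired
  greedily by polygon IoU. Caption tokens are lowercased, split on
  whitespace and commas, trailing periods stripped; terminology ids are
  detokenized to their display names first so id-coded and free-text
  captions are comparable. BLEU uses clipped n-gram precision, the
  standard brevity penalty and an unsmoothed geometric mean: any zero
  precision gives 0, and 1 is attained exactly by identical captions.
  (An epsilon smoothing mode is selectable.)

Polygon IoU — used for caption pairing and audit matching — is computed by
rasterization rather than exact clipping: at desk scale the raster error
is negligible and the computation is deterministic and dependency-free.
Audit diffs match regions at IoU ≥ 0.5, classify the rest as additions or
removals, and flag matched regions whose labels or captions changed.

## Behavioral traces and attention heatmaps

Traces record field-of-view changes, magnification, pencil switches,
voice and edit events. Dwell follows *last-event-holds* semantics: each
fov/magnification event opens an interval closed by the next one (voice
and edit events do not close intervals). The viewport rectangle is the
screen size (default 1920×1080) divided by the magnification, centered on
the fov center, clipped to the slide. Intervals longer than 120 s are
truncated as idle time — an unattended session would otherwise dominate
every statistic; the cap, screen size and cell size are all configurable
since recording hardware varies. Heatmaps accumulate each interval's
dwell into every grid cell its rectangle covers (cells default to 256 px,
aligning heat cells with patches); the invariant `Σ cells = Σ dwell ×
covered cells` is conserved exactly and tested.

## Lesion clustering and caption bags

Predicted-abnormal patches are clustered with classical DBSCAN on their
grid coordinates. Defaults: `eps = 1.5` (the 8-neighborhood of a patch is
adjacent, so touching abnormal patches merge) and `min_samples = 4`
(suppressing isolated false positives). Cores expand in lexicographic
scan order and border points join the first cluster that reaches them;
cluster ids are canonicalized by each cluster's smallest member, so the
output is invariant under input permutation. Caption bags cap each
cluster at a fixed size (64 for training, 256 for prediction, following
the published experiment settings), sampling uniformly without
replacement, with optional with-replacement padding for training.

## The synthetic cohort generator

The generator emulates the *structure* of a decision-to-reason annotated
colorectal cohort, not its biology: white background, one blobby tissue
region per slide in smooth pale pink, lesion polygons textured by class
(smooth / striped / speckled value noise), reason regions nested inside
lesions, captions drawn from the lesion subtype's terminology subtree,
and bundles over reason regions sharing a subtype. Defaults: caption
lengths are `1 + Poisson(3.4)`, giving at least one term and mean 4.4 —
the published cohort's mean caption length; the class mixture (25%
normal, 12.5% adenoma, 62.5% adenocarcinoma slides) follows the rough
published cohort proportions; 2–4 decision regions and 1–3 reason
features per region keep slides desk-sized. Tumor-slide lesions are
placed on disjoint slots, so region labels — and therefore the flip-rate
recovery analysis — are not confounded by overlaps.

Perturbed second annotators flip each region's label with probability `f`
to a uniformly different same-level label (re-drawing subtype and reasons
under the new class so the document stays valid) and jitter polygon
vertices by bounded uniform offsets, logging every change; the log is the
ground truth for the audit-diff oracle tests. Traces place viewport
centers inside lesions with the configured probability (default 0.8),
echoing the observation that annotators dwell longest on difficult lesion
areas.

All randomness flows from one seed through named substreams (per slide,
per perturbation, per trace), so artifacts regenerate independently and
whole cohort directories are byte-identical across runs.

**What passing tests show — and what they do not.** The generator's
textures are procedural; its polygons are star-shaped blobs; its captions
are draws from the terminology, not clinical prose. Tests on this cohort
therefore certify the *machinery* — formats, geometry, metrics,
determinism, parameter recovery — not performance on real H&E slides,
which varies with staining, scanner and case difficulty.

## Problem sizes and numerical choices

The test suite and the acceptance script run on desk-scale inputs chosen
to keep Monte-Carlo estimates tight while staying fast: 192–512 px
slides, 32 px patch grids, cohorts of 2–16 slides, 240 s traces, 3600
pixel stain images. Where an estimate is stochastic (flip-rate recovery,
dwell bias, caption mean), assertions use explicit Monte-Carlo confidence
intervals at the natural granularity — label flips act on whole regions,
so the flip-recovery interval is scaled by the region count, not the
patch count. Degenerate inputs have defined behavior throughout:
single-bin histograms raise a distinct condition (and an all-white slide
is simply maskless), rank-1 stain clouds are flagged rather than
inverted, empty-vs-empty Dice is 1 with a flag, and constant-rater kappa
is 1 with a flag.

## Known limitations

* Polygon IoU and pixel Dice are raster approximations; at very small
  region sizes relative to the downsample they lose precision.
* DBSCAN is exact but quadratic in point count — appropriate for per-slide
  patch grids, not for millions of points.
* The optional pyramidal-slide path reads a single pre-extracted level;
  multi-resolution IO is out of scope.
* Voice is carried as references only; no audio processing.
* Kappa at the class level is uninformative on single-class slides (one
  rater is effectively constant); the subtype-level kappa and Dice carry
  the signal there, as the README example shows.
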