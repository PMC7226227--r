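---
title: "Methods: automated TMEM doorway scoring"
author: "TMEMscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated TMEM doorway scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TMEMscore)
```

## The biological quantity

A TMEM (Tumor MicroEnvironment of Metastasis) doorway is a microanatomical
structure in which three cells are in direct, stable contact: a tumor cell
overexpressing the actin-regulatory protein Mena, a perivascular
macrophage, and a blood-vessel endothelial cell. TMEM doorways are the
sites where tumor cells intravasate, and their density in a primary breast
tumor is prognostic for distant metastasis. The clinical readout, the
*TMEM score* (also called MetaSite score), is the number of TMEM doorways
summed over the ten highest-density high-power fields (HPFs) of the
invasive tumor region, with published risk cutoffs at 6 (low vs
intermediate) and 23 (intermediate vs high).

Slides are triple-immunostained — CD31 with Vector Blue for endothelium,
CD68 with DAB for macrophages, pan-Mena with Fast Red for tumor cells —
over a light-green counterstain. TMEMscore reproduces the automated
digital-pathology reading of such slides: it classifies every pixel,
reconstructs candidate cell objects, identifies the triple-contact
configurations morphometrically, and scores the slide the way a
pathologist would, field by field.

## Pipeline and model assumptions

### 1. Stain feature channels

RGB is converted to optical density per channel,
$od = -\log_{10}\!\big((v+1)/256\big)$, the space in which chromogen
absorbances combine approximately linearly (Beer–Lambert). Each pixel's OD
vector is decomposed onto four unit stain directions (three chromogens
plus the counterstain; modeling the counterstain as a fourth direction
stops the background leaking into the signal channels).

With four directions in a three-dimensional OD space the unconstrained
least-squares decomposition is not unique, so the package solves the exact
non-negative least-squares problem instead, by enumerating candidate
supports of size at most three (the NNLS optimum always admits such a
support). Ties resolve to the smallest, earliest support, which keeps a
pure-stain pixel on its own channel. For a full-column-rank stain matrix
(up to three stains) this reduces to ordinary least squares with negative
concentrations clipped to zero. Each channel is then median-filtered
(radius 1 px by default, i.e. a 3×3 kernel; the filter is exact, with
replicated image edges) to suppress single-pixel noise before
classification.

The default stain matrix is fitted to the synthetic renderer's reference
colors. For real slides the chromogen reference colors are a configuration
input (`stains:` in the YAML config); automatic stain-vector estimation is
out of scope.

### 2. Linear Bayesian pixel classification

A Gaussian linear discriminant model — per-class means, one pooled
covariance, class priors — assigns each pixel to one of five classes:
macrophage, darkly stained tumor, lightly stained tumor, vessel, and
stroma/background. Two tumor classes absorb staining-intensity variation;
they are merged before morphometry. The shared covariance makes every
decision boundary linear; classification is the posterior argmax
$\delta_k(x) = x^\top\Sigma^{-1}\mu_k - \tfrac12\mu_k^\top\Sigma^{-1}\mu_k
+ \log\pi_k$, with ties broken to the lowest class code.

Choices: the pooled covariance is regularized by `1e-6 * mean(diag(cov))`
on the diagonal so degenerate training sets stay invertible; priors
default to uniform because annotation-guided sampling is not
frequency-representative of tissue composition. Training happens once
(`trainPixelClassifier()` on image/label-mask pairs), the model is
serialized to JSON, and applied frozen thereafter.

### 3. Morphometry and the reclassification cascade

Discrete conventions, fixed everywhere: 8-connectivity for components and
adjacency; a boundary pixel is an object pixel with at least one
non-object 8-neighbour (image edges count as outside); a contact fraction
is the share of an object's boundary pixels 8-adjacent to the neighbour
class, which cancels the unit of perimeter.

Object formation smooths each merged class mask by morphological closing
with a disk (the dilate-then-erode boundary smoothing; radius 0.75 µm
≈ 2 px at the default calibration — the radius is not dictated by the
method, so it is a config value). Closing can make class masks overlap;
overlaps resolve by the fixed priority vessel > macrophage > tumor >
stroma (rarest structure wins), keeping the label map a partition.

Size filters then remove implausible objects, with strict inequalities
exactly as stated by the method: vessels and macrophage aggregates
> 800 µm²; tumor fragments < 10 µm²; stroma < 400 µm²; macrophage and
vessel particles < 5 µm². An object of exactly 800 or exactly 5 µm²
survives.

The cascade runs in order on the filtered objects:

(a) vessels with ≥ 2% macrophage perimeter contact become
    vessel–macrophage complexes;
(b) macrophages in contact (any contact > 0 — the method states no
    percentage here) with such a complex become macrophage–vessel
    complexes;
(c) macrophage–vessel complexes ≥ 40 µm² with ≥ 8% tumor and ≥ 20% vessel
    contact become large TMEM-associated (TA) macrophages; those < 40 µm²
    with ≥ 10% and ≥ 10% become small TA-macrophages;
(d) vessel–macrophage complexes with ≥ 20% tumor contact and ≥ 20%
    contact with TA-macrophages become TA-vessels;
(e) everything else is discarded.

Two ambiguities were decided once: "vessel contact" in (c) and "tumor
contact" throughout are measured against the union of all post-filter
vessels / tumor (not just the paired object), and contacts are computed
once on the post-filter masks — step (d)'s TA-macrophage mask is the
union of large and small TA-macrophages recomputed after (c).

Each TA-vessel is finally dilated by a Euclidean disk of 50 µm (140 px at
0.357 µm/px) into a *TMEM marker object* that emulates the circles drawn
in manual scoring; markers keep one-to-one parentage and are not merged
when they overlap. (Manual scoring uses a 60 µm *diameter* circle; the
automated method's 50 µm *radius* is retained as stated.)

### 4. Tiling, ranking, scoring

The ROI (a pathologist-drawn mask or polygon set restricting analysis to
invasive tumor; pixels outside it are treated as background) is covered by
a disjoint grid of HPF-sized tiles anchored at the ROI bounding box,
~300 × 400 µm each (the manual-microscopy HPF of 439 × 330 µm² is
available as a preset). Each TMEM marker is counted in exactly one tile —
the tile containing its parent TA-vessel centroid under the half-open
pixel convention — so an overlapping marker can never be double-counted.
Tiles with less than half their area in the ROI are excluded (the 0.5
floor approximates a pathologist picking fields inside tumor nests; it is
configurable). Tiles are ranked by count, ties broken by row-major index,
and the final score is the sum over the top 10 (all tiles when fewer
exist). Disjoint rather than overlapping fields were chosen; overlapping
ranking would only inflate counts shared between neighbouring fields.

Three quantification metrics are reported per slide: the TA-vessel count
(the primary score basis — approximately one per doorway, the scale
pathologists use), the TA-macrophage count, and the total
TA-macrophage/TA-vessel interface length in µm (boundary-pixel count ×
pixel size). Risk categories use the published cutoffs with the boundary
convention low ≤ 6 < intermediate ≤ 23 < high; the method does not state
the boundary handling, so it is exposed in the config and echoed in every
report.

### Calibration

The source method reports both a scanner pixel size of 0.12 µm and a 50 µm
dilation equal to 140 px (0.357 µm/px); the two are mutually inconsistent,
so physical calibration is a required configuration value, never
hardcoded. The default is 0.357 µm/px, the value consistent with the
dilation specification and with all pixel-level constants above.

## The synthetic slide generator

No slides or accessions from the original cohort are available, so
validation uses synthetic triple-IHC-like slides with known ground truth
(`generateSlide()`):

* stroma background, two-tone tumor nests (radius 16 µm), vessels
  (disks, 50 µm²), macrophages (25 µm² half-annuli hugging the vessel),
  rendered as exact alias-free discrete shapes so contact fractions are
  exactly computable;
* each planted triad's contact fractions are measured at build time with
  the package's own adjacency oracle and must clear every cascade gate
  with at least a 2× margin, or generation aborts;
* five distractor kinds each violate exactly one gate: an isolated
  macrophage, a vessel without macrophage, a vessel–macrophage pair with
  no tumor contact, a macrophage aggregate of 1000 µm² (> 800), and a
  3 µm² vessel fragment (< 5);
* structures sit on a site grid (≈143 µm pitch) that keeps every pair of
  structure edges separated by more than 2 × (50 µm + smoothing radius),
  so markers and contacts never interact; overcrowded specs are rejected;
* additive Gaussian RGB noise (sd 8 of 255 by default — enough to spread
  each class color over thousands of distinct RGB values while keeping
  classes separable, similar to camera shot noise) is applied after
  geometry, so the ground-truth label mask is exact and noise can never
  move a class boundary.

What the generator does *not* emulate: staining gradients and batch
variation, out-of-focus regions, folds and retraction artifacts, nuclear
texture, partial-volume (anti-aliased) boundary pixels, and realistic
vessel/macrophage shape diversity. Green tests on synthetic slides
therefore demonstrate the correctness of the morphometric logic and the
determinism of the pipeline, not clinical-grade robustness on real
histology; for real slides the stain matrix and classifier must be
re-fitted to measured chromogen colors and annotated fields.

Default canvases are whole multiples of the HPF tile (e.g. 2240 × 2520 px
= 2 × 3 tiles at 0.357 µm/px) so every tile is fully eligible;
`slideSpecForCount()` picks the smallest preset (1 to 6 tiles) that holds
a requested number of structures under the separation invariant.

## Numerical choices

* Median filter: exact (selection, not histogram approximation),
  replicated edges, compiled for speed; identity on constant regions and
  idempotent on plateaus larger than the kernel.
* Unmixing is performed once per distinct RGB triple and broadcast, which
  is exact for 8-bit input.
* NNLS support enumeration compares residuals with a 1e-12 tolerance;
  earlier/smaller supports win ties, making the decomposition
  deterministic.
* 8-connected labelling uses a 4-connected pass plus a diagonal
  union-find merge; perimeter is the boundary-pixel count (the contact
  *ratio* is what the cascade consumes, so no perimeter unit calibration
  is needed).
* Marker dilation thresholds a per-object Euclidean distance transform at
  the radius in pixels (`round(50 / mpp)`), computed on a cropped window
  with a safety halo.
* Degenerate inputs: empty ROIs, empty object sets, all-zero tile counts,
  fewer tiles than top-k, and constant truth panels (rank correlations
  undefined → reported `NA`) are all handled explicitly and tested.

## Evaluation harness and problem sizes

`runEval()` generates a panel of slides, trains once, scores each slide
twice, and reports per-slide truth vs recovered counts, the two-run
Pearson repeatability (1.0 exactly, since the pipeline is deterministic),
and the pairwise Spearman matrix of the three metrics. The package's own
validation panels use 12 slides (scored twice) for repeatability, 40
slides with planted counts spanning 0–30 for metric concordance, and 50
noise-free slides for exact plant-and-recover; smaller canvases are used
where the planted counts allow, which changes nothing but canvas area.

## Known limitations

* In-memory processing only: slides at whole-slide-scanner scale
  (multi-gigapixel) would need tile streaming with halos, which this
  package does not implement.
* No automatic stain-vector estimation; reference colors are inputs.
* The pixel classifier is linear by design (it mirrors the method); it
  will not rescue poorly separated chromogens.
* Pyramidal/proprietary WSI formats are out of scope; inputs are plain
  PNG/TIFF.
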