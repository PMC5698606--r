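---
title: "Shape and boundary similarity features for nucleus morphology classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and boundary similarity features for nucleus morphology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomorph)
```

## The problem

In H&E-stained liver pathology, hepatocellular carcinoma (HCC) nuclei
differ from normal hepatocyte nuclei chiefly in morphology: they tend to
be enlarged, more elongated and more irregular in outline. Color and
texture cues are notoriously unstable across staining batches and
scanners, so this package classifies nuclei from their **binary masks
alone**. The pipeline is:

1. **Segmentation (CPS).** A pathology tile is coarsely thresholded,
   connected regions are filtered by circularity (round, isolated seeds
   are kept), and a fixed-size patch is cut around each region center —
   one nucleus per 100×100 patch.
2. **Alignment.** Each mask is mapped into a *uniform standard space*:
   centroid at the patch center, foreground area ≈ 1000 px, major
   principal axis horizontal. This removes translation, scale and
   rotation before shapes are compared.
3. **Shape-similarity features.** A *shape library* of aligned reference
   nuclei (80 normal + 80 HCC by default) is fixed; every query nucleus
   is scored against each entry with overlap coefficients — Dice,
   Jaccard, precision, recall — giving up to 4 × 160 = 640 features. The
   Jaccard block alone (160 features) is the strongest single family.
4. **Boundary-similarity features.** On a pose-aligned (centered and
   rotated, *not* rescaled) mask, the moment-equivalent ellipse is
   fitted; k = 12 template points are placed on it at π/6 polar-angle
   steps, anticlockwise from the positive horizontal axis
   (x = a cos θ, y = b sin θ); each template point is snapped to the
   nearest nucleus boundary pixel, yielding 12 ordered landmarks. All
   C(12,3) = 220 landmark triangles are encoded by interior-angle
   cosines — a scale-free description of boundary geometry.
5. **Classification.** A bootstrap ensemble of decision trees (random
   forest) votes by majority; accuracy, sensitivity and specificity are
   estimated by stratified 10-fold cross-validation, with HCC as the
   positive class.
6. **Feature selection.** Library nuclei are ranked by single-column
   cross-validated accuracy and the library is regrown incrementally
   (30, 40, 50, … entries); boundary landmarks are ranked by how often
   they appear as vertices of the best-performing triangles, and the
   triangle block is restricted to the top-p landmarks (C(p,3)
   features). The canonical optimal set combines 80 Jaccard features
   with the 56 triangles over the 8 best landmarks — 136 dimensions.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `patch_size` | 100 px | patch side; one nucleus per patch |
| `threshold` | `"auto"` (Otsu) | coarse binarization cut; Otsu is parameter-free and the synthetic images are strongly bimodal |
| `min_circularity` | 0.85 | CPS keeps regions with 4πA/P² strictly above this; keeps round isolated seeds, rejects debris and clumps |
| `min_area` | 30 px | discards speckle before the circularity test |
| `n` | 50 px | pre-resize crop side around each center |
| `target_area` | 1000 px | standard-space foreground area |
| `n_per_class` (library) | 80 | library entries per class |
| `k` | 12 | boundary landmarks; features are C(k,3) triangles |
| `initial_angle` | 0 | polar phase of the first template point |
| `n_trees` | 500 | forest size for final models (100 for single-column ranking, where stump ensembles stabilise quickly) |
| `folds` | 10 | stratified cross-validation folds |
| `top_frac` | 0.5 | fraction of triangles whose vertices are counted when ranking landmarks |

## Numerical and design choices

**Connectivity.** Components are labelled 8-connected (diagonal
neighbours merge), so thin tilted boundaries are not split. The
underlying 4-connected labeller is augmented with a union–find pass over
diagonal label adjacencies.

**Perimeter and circularity.** The perimeter is the chain-code length of
the traced object contour (axial steps 1, diagonal steps √2). On this
estimator a rasterized disk scores ≈ 0.91, a filled square ≈ 0.84
(continuum π/4 ≈ 0.785), and a 1-px line ≈ 0.11; a single pixel, whose
traced contour has zero length, is assigned circularity 1 by convention.
Circularity is scale-stable to well under 0.05 between radius-10 and
radius-40 disks.

**Crop convention.** An n-sided crop centered at pixel c spans rows
`c − ⌊n/2⌋ … c − ⌊n/2⌋ + n − 1` (1-based pixel centers), so even n is
reproducible. Mask patches are resized nearest-neighbour (binarity
preserved) and reduced to the single component at the patch center;
intensity patches are resized bilinearly.

**Alignment.** The similarity map a′ = σR a + T is applied by pulling
every output pixel back through the inverse map, with the rotation pivot
at the foreground centroid. Each output pixel is sampled on a 2×2
subpixel grid and re-binarized at coverage ½; plain pixel-center
sampling leaves enough boundary quantization noise in the second moments
to destabilise the orientation estimate. Because rasterization shifts
area, angle and centroid slightly, up to 8 corrective passes re-estimate
the residuals and re-rasterize *from the original mask* (errors do not
compound); the angle step is halved whenever the residual changes sign,
which suppresses the limit cycles that full-step updates can enter. The
contract after alignment: area within 5% of 1000 px, residual principal
angle below 0.03 rad, centroid within 0.5 px of the patch center.

**Orientation ambiguities.** The principal axis is defined modulo π and
canonicalised to (−π/2, π/2]; neither the resulting 180° ambiguity nor
mirror reflection is resolved — second moments cannot see either. For
π-symmetric shapes both collapse, which is why the equivariance tests
use even-harmonic synthetic masks; for strongly asymmetric nuclei two
rigidly rotated copies can align to 180°-rotated standard poses. This is
a known limitation shared by any principal-axis normalisation.

**Overlap features.** The coefficients are evaluated exactly on pixel
sets; the query mask plays the segmentation-region role (SR) and the
library entry the reference role (TR), which fixes which of
precision/recall is which. Dice = 2J/(1+J) holds to machine precision by
construction. Queries whose area is outside 5% of the library's target
area are refused — comparing unaligned masks silently would be the
pipeline's most insidious failure mode. Feature columns are named
`metric.libraryid` and the library order is persisted, so columns are
stable and permutation-covariant with the library.

**Boundary extraction.** The default is the morphological inner gradient
(mask & ¬erode(mask)): deterministic, parameter-free, exactly one pixel
wide, and closed. A Canny-style backend (Gaussian blur, Sobel,
non-maximum suppression, hysteresis) is provided for users who prefer
classic edge detection, at the cost of two hysteresis thresholds and a
smoothing scale that a binary mask does not really need. Holes are
filled first; a multi-component mask is an error, not a warning.

**Triangles.** Triples are enumerated in lexicographic order (i < j < k).
Interior angles come from the law of cosines on squared side lengths,
with cosine arguments clamped to [−1, 1]. In the default `"paper"` mode
one cosine per triangle is kept (the angle at the middle vertex j),
giving the canonical dimensions 220 / 56 / 136 / 860; `"full"` mode
keeps the angles at j and k (two per triangle) — the third is redundant
because interior angles sum to π. Degenerate triples (coincident or
collinear landmarks, which occur when several template points snap to
the same boundary pixel) take limiting cosine values and are counted in
the `degenerate` attribute rather than erroring. Landmark ties are
broken toward the smallest (row, col), making landmark selection exactly
reproducible against brute-force search.

**Scaling and the boundary block.** Only pose alignment (translation +
rotation) precedes boundary features: the fitted a and b are those of
the original segmented nucleus, and triangle angles are scale-free
anyway, so area normalisation would only add resampling noise.

**Voting.** Ensemble predictions are computed explicitly as the majority
over per-tree votes; exact ties (possible with an even tree count) go
deterministically to the first class level (`normal`). The forest
backend's own aggregation is used only as a cross-check in the test
suite.

**Subset growth.** The accuracy curve over library sizes 30, 40, 50, …
is evaluated on shared stratified folds. Two picks are reported:
`best_size`, the argmax with ties to the smaller size, and
`best_size_1se`, the smallest size within one standard error of the
maximum. On realistic curves accuracy saturates and then wanders in
cross-validation noise, so the argmax is nearly uniform over the
plateau; the one-standard-error rule — standard practice in tree
pruning and penalised regression — identifies the elbow stably and is
the pick the package recommends.

## What the synthetic generator does and does not emulate

No clinical images ship with the package; a two-class generator stands
in for them. A synthetic nucleus is a radially perturbed ellipse,
r(t) = r_ellipse(t)·(1 + Σ_h ε_h cos(h t + ψ_h)) with harmonics 2–5, so
every mask is star-shaped and single-component. Class archetypes encode
the qualitative pathology contrast — normal: aspect 1.0–1.4, roughness
ε ≤ 0.05, area 600–1200 px; HCC: aspect up to 2.2, ε 0.10–0.30, area
800–2600 px. Draws whose maximum radius cannot fit the patch (the
extreme corner of the HCC ranges) are rejected and redrawn. One global
seed fans out to per-nucleus substreams, so datasets are reproducible
and extensible. Composite test images place round, mildly perturbed
nuclei (the regime the CPS circularity gate is designed for) without
overlap on a bright noisy background.

What this emulates: the balanced one-nucleus-per-patch regime, a
morphological class contrast, ground-truth centers for segmentation
scoring. What it does **not** emulate: staining variation, touching and
overlapping nuclei, segmentation errors correlated with class, chromatin
texture, and the long-tailed shape diversity of real tissue. Passing the
synthetic benchmark therefore demonstrates that the implementation
separates classes whose morphology differs in the stated way — not that
the reported accuracy transfers to clinical data.

## Problem sizes used in the reference experiments

The package's reference experiment (`synthetic_benchmark()`) uses 200
nuclei per class plus an independent 80-per-class library pool, Jaccard
+ triangle features, a 500-tree forest and 10-fold cross-validation; the
label-shuffled control reruns the identical pipeline with permuted
labels and should sit at chance. Alignment contracts are exercised over
50 random nuclei; overlap and triangle oracles on 20×20 masks and random
landmark sets; selection recovery on planted-signal tables (50 signal
columns among noise, 5 seeds). These sizes were chosen to estimate each
quantity with comfortable margins while keeping the whole suite quick to
run; `scripts/acceptance.R` recomputes all of them from scratch at a
user-supplied seed.

## Known limitations

- Overlapping or touching nuclei are out of scope; CPS assumes round,
  isolated seeds and the circularity gate drops clumps.
- The 180° and mirror ambiguities of principal-axis alignment are
  unresolved (see above).
- Stain deconvolution and color normalisation are deliberately absent —
  the premise of the method is that binary masks suffice.
- With very irregular boundaries several template points can snap to the
  same boundary pixel, producing degenerate triangles; these are flagged
  but retained.
- The "suitable threshold" of coarse segmentation is Otsu's by default;
  strongly non-bimodal tiles may need an explicit threshold.
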