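# nucleomorph

Morphological recognition of normal versus hepatocellular carcinoma
(HCC) nuclei from binary nucleus masks.

Pathology color and texture are fragile across staining batches and
scanners; nucleus **shape** is not. `nucleomorph` implements a complete
binary-mask morphology pipeline for H&E liver tiles:

- **Center-proliferation segmentation (CPS):** coarse (Otsu)
  binarization, 8-connected components, a circularity gate
  (4πA/P² > 0.85) that keeps round isolated nuclei, and extraction of
  one 100×100 patch per nucleus center.
- **Uniform standard space:** each mask is aligned by the similarity
  map a′ = σRa + T — centroid to patch center, area scaled to
  σ = √(1000/area) ≈ 1000 px, major principal axis rotated horizontal.
- **Shape-similarity features:** every aligned nucleus is scored
  against a fixed shape library (80 normal + 80 HCC aligned references)
  with Dice 2|A∩B|/(|A|+|B|), Jaccard |A∩B|/|A∪B|, precision and
  recall — up to 640 features, 160 per coefficient.
- **Boundary-similarity (BF) features:** on a pose-aligned mask, k = 12
  points are placed on the moment-equivalent ellipse
  (x = a cos θ, y = b sin θ, θ in π/6 steps anticlockwise from the
  positive x-axis), snapped to the nearest boundary pixels, and all
  C(12,3) = 220 landmark triangles are encoded by interior-angle
  cosines (law of cosines; scale-free).
- **Random-forest voting classifier** (explicit per-tree majority
  vote), ACC / SEN / SPE evaluation with HCC as the positive class, and
  stratified 10-fold cross-validation.
- **Feature selection:** per-library-nucleus ranking with incremental
  library growth, and landmark ranking by triangle occurrence; the
  canonical optimal set is 80 Jaccard + C(8,3) = 56 triangle features
  (136 dimensions).
- **Synthetic-nucleus generator:** two morphological classes of
  radially perturbed ellipse masks, plus composite multi-nucleus tiles
  with ground-truth centers, so the full pipeline can be exercised and
  benchmarked without clinical data.

## Worked example

```r
library(nucleomorph)

# a library pool and an analysis set of synthetic nuclei
pool <- generate_dataset(n_per_class = 40, seed = 2)
lib  <- build_shape_library(pool$masks, pool$labels, n_per_class = 40, seed = 3)
lib
#> <shape_library: 80 entries (40 normal + 40 HCC), target area 1000 px>

data <- generate_dataset(n_per_class = 60, seed = 1)

# Jaccard block (80 columns) + 220 triangle features per nucleus
tab <- feature_table(data$masks, data$labels, library = lib, metrics = "JI")
dim(tab)
#> [1] 120 301

cv <- cross_validate(tab, folds = 10, n_trees = 500, seed = 1)
cv$summary
#>  metric  mean         sd
#>     ACC 0.975 0.04025382
#>     SEN 0.950 0.08050765
#>     SPE 1.000 0.00000000
```

120 nuclei, 300 features (80 JI + 220 BF) and a label column; the
synthetic classes are separated at 97.5% cross-validated accuracy, with
sensitivity 0.95 (HCC recall) and specificity 1.00 (normal recall).

The alignment and overlap primitives are directly accessible:

```r
m <- align_mask(data$masks[[1]])
m$transform
#> <alignment_transform dx=-0.02 dy=0.11 scale=1.022 angle=-1.204 rad>
sum(m$mask)          # standard-space area
#> [1] 1000
overlap_metrics(m$mask, lib$masks[[1]])
#> dice 0.9399  jaccard 0.8867  precision 0.9390  recall 0.9409
```

A thin command-line front-end over the same functions ships in
`inst/cli/nucleomorph.R`:

```sh
Rscript inst/cli/nucleomorph.R synth-image --n-nuclei 20 --size 512 --seed 1 --out tile/
Rscript inst/cli/nucleomorph.R segment --input tile/image.png --out patches/
Rscript inst/cli/nucleomorph.R features --masks patches/manifest.csv \
    --library library/manifest.csv --metrics JI --out features.csv
Rscript inst/cli/nucleomorph.R cv --features features.csv --folds 10 --seed 1
```

## Scope

The package operates on binary masks; stain deconvolution, color
normalisation and overlapping-nucleus splitting are out of scope. See
the methods vignette (`vignettes/nucleus-morphology.Rmd`) for the model,
parameter rationale, numerical choices and known limitations.
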