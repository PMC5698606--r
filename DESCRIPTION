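Package: nucleomorph
Title: Shape and Boundary Similarity Features for Nucleus Morphology
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphological recognition of normal versus hepatocellular
    carcinoma (HCC) nuclei from binary nucleus masks. Implements
    center-proliferation segmentation of pathology images into one-nucleus
    patches, rigid-plus-scale alignment of masks into a uniform standard
    space, overlap-based shape-similarity features (Dice, Jaccard,
    precision, recall) scored against a curated nucleus shape library,
    triangle-angle boundary-similarity features built from ellipse-template
    landmarks, random-forest classification with majority voting, and the
    accompanying feature-selection procedures (per-library-nucleus ranking
    with incremental library growth, boundary-landmark ranking by triangle
    occurrence, stratified cross-validation). A synthetic-nucleus generator
    provides two morphological classes of binary masks and composite
    multi-nucleus test images with ground truth, so the full pipeline can
    be exercised and benchmarked without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    ranger,
    png,
    stats,
    tools,
    utils
Suggests:
    tiff,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
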