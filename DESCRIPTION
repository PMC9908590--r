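Package: wsianno
Title: Hierarchical Decision-to-Reason Annotation Toolkit for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hierarchical decision-to-reason annotation of whole-slide
    histopathology images: an annotation data model with unified terminology
    (class, subtype, reason), validation and interchange formats (JSON, TSV,
    GeoJSON, JSON Lines, CSV), a patch extraction pipeline with Otsu tissue
    masking, Macenko stain normalization and central-pixel labeling,
    multi-level annotator-agreement metrics (Cohen's kappa, Dice, BLEU),
    audit diffs, behavioral-trace attention heatmaps, density-based lesion
    clustering with caption bags, and a synthetic fixture generator so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    readr,
    stringr,
    ggplot2,
    png,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
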