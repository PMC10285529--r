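Package: netquant
Title: Quantification of Neutrophil Extracellular Trap Formation in
    Two-Channel Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments regions of interest (ROIs) in paired total-DNA and
    extracellular-DNA fluorescence channels by thresholding and connected
    components, computes per-ROI intensity, Laplacian-of-Gaussian and shape
    features, and classifies each ROI into NETosis stages (PMN, RND, RUP,
    PER neutrophils), NETs, bacterial clumps and extracellular artifacts
    with a smooth interval-membership score and an unambiguous-assignment
    decision rule. Produces per-image summaries with a quality score,
    batch reports, bounding-box evaluation against Pascal-VOC annotations
    (IoU matching, confusion matrix, precision/recall), and a seeded
    synthetic-scene generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
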