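Package: edgewater
Title: Leading-Edge Image Quantification for Migrating T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify how ion- and water-influx signalling shapes the
    leading edge of migrating T cells from multi-channel fluorescence
    time-lapse data: cell segmentation, tracking and shape metrics with the
    exclusion rules used in under-agarose and collagen assays; 12-bin polarity
    profiles, perimeter polarization and MPAct/CaaX membrane-proximal actin
    ratios; membrane-to-F-actin spacing along the leading edge from
    straightened edge bands; kymograph-based retrograde actin flow; z-stack
    and Coulter-style cell volumetry; medium tonicity design; ICP-MS and NMR
    normalization chains; and the study-style statistics (exact Mann-Whitney,
    Kruskal-Wallis, Pearson correlation, two-stage step-up FDR). A synthetic
    movie generator with full per-cell ground truth supports end-to-end
    validation of every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
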