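Package: sgquant
Title: Quantitative Stress-Granule Image Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying stress-granule (SG) formation in
    multi-channel confocal immunofluorescence images of epithelial
    monolayers. Generates synthetic 2D confocal regions of interest with
    known ground truth (elliptical DAPI nuclei, diffuse cytoplasmic marker
    signal, planted granules, constant additive background, Poisson and
    Gaussian noise); segments nuclei from the DAPI channel and granules
    from a marker channel with watershed separation of touching puncta;
    computes per-granule, per-ROI and nuclear/cytoplasmic fluorescence
    metrics; implements smoke-extract dose arithmetic (concentration from
    optical density, dose per cell, constant dose-per-cell scaling) and an
    additive background correction for fold changes; and provides the
    statistical layer used for condition comparisons (ROUT outlier removal,
    Kruskal-Wallis with Dunn's post hoc test, Welch's t, Brown-Forsythe and
    Welch ANOVA, Kolmogorov-Smirnov, blot normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
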