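Package: adiposizer
Title: Automated Adipocyte Sizing from Whole-Slide Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated measurement of white adipocyte cross-sectional size
    from whole-slide images of H&E-stained adipose tissue. Implements a
    fixed, scriptable segmentation recipe (triangle auto-thresholding,
    binary erosion, circular-median outlier removal), connected-component
    particle analysis with physical-unit area and circularity gates,
    conversion of areas to equivalent circular diameters with per-sample
    quality-control rules, method-comparison statistics (Bland-Altman
    agreement, paired tests, Meng's Z for correlated correlations) and
    clinical adiposity indices (HOMA-IR, VAI). A synthetic adipose-tissue
    generator with known per-cell ground truth supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
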