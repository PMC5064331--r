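Package: msidiff
Title: Subfield-Resolved Differential Lipid Analysis for MALDI Imaging
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, tested reimplementation of a region-of-interest
    differential analysis workflow for MALDI imaging mass spectrometry
    lipidomics. Provides a synthetic paired-study phantom generator with
    known region-specific lipid changes, continuous/processed imzML
    reading and writing, spectral preprocessing (alignment to a control
    m/z list, morphological top-hat baseline removal, total-ion-count
    normalization, windowed peak extraction), spatial segmentation by
    k-means over denoised feature images, per-ROI paired
    receiver-operator characteristic (ROC) analysis with a cross-pair
    consistency filter, percent-change quantification, and ion-image
    and summary-table reporting with m/z-tolerance lipid annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    grDevices,
    png,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
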