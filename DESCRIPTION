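Package: neurquant
Title: Quantification of Micropatterned Neuruloid Colonies and Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image and expression quantification for radially organized
    micropatterned stem-cell colonies (neuruloids). Provides ground-truthed
    synthetic data generators (colony images with Gaussian-blob nuclei, central
    marker disk and peripheral marker ring; negative-binomial single-cell count
    matrices with planted lineages, marker genes, gene-set shifts and
    quality-control violators), multi-channel TIFF stack handling with
    maximum-intensity projection, colony detection and cropping, seeded-watershed
    nuclear segmentation with per-nucleus median intensities, radial intensity
    profiles with edge averages and half-maximum domain radii, marker area
    fractions and mitotic indices, a single-cell arm (QC filtering, log10
    normalization, covariate residualization, marker-signature lineage scoring,
    hurdle-model differential expression and permutation gene-set enrichment),
    and group-comparison statistics with condition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Matrix,
    Rcpp,
    car,
    fgsea,
    methods,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
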