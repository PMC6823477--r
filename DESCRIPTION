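Package: topohet
Title: Topographic Heterogeneity Analysis for Multiplexed
    Immunofluorescence of PDX Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of spatial phenotypic heterogeneity in
    patient-derived xenograft (PDX) tumor cohorts profiled by multiplexed
    immunofluorescence and bulk molecular assays. Provides a synthetic
    cohort generator with known ground truth at every spatial scale;
    correction of additive-background / periodic-stripe imaging artifacts;
    DAPI exposure rescaling and replicate-section percentile matching;
    adaptive-threshold tissue masking (cellular, stromal, tumor); recursive
    multi-scale decomposition of biomarker pixel-intensity variance across
    the hierarchy dataset - model - tumor - sector - image - region -
    microenvironment - cellular - subcellular; block-based unsupervised
    phenotype profiling; sampling-design confidence curves for
    tissue-microarray-style sub-sampling; and the tabular side-pipeline
    (sequencing QC gates, RPM normalization, mouse-variant exclusion,
    spike-in flagging, growth-rate estimation, scale-stratified profile
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
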