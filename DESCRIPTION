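Package: mechanomics
Title: Spatial Mechanomics of Bone Healing: Micro-FE Strain Mapping and
    Strain-Stratified Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for spatial mechanomics of the healing bone
    fracture callus: time-lapsed voxel bone morphometrics (remodeling
    classification, BV/TV, formation and resorption rates, defect size),
    voxel-based hexahedral micro-finite-element analysis of uniaxial
    compression with effective-strain mapping and adaptive load
    optimization, embedding of 2D spatial-transcriptomics spot grids into
    the 3D strain field with strain-region classification, and strain-
    stratified expression statistics (median-of-ratios normalization,
    negative-binomial likelihood-ratio differential expression, CV-based
    gene ranking, gene-set scoring). Synthetic phantom and count
    generators provide ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
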