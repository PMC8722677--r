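Package: cardiopheno
Title: Multimodal Phenotyping of Heart-Field-Specific Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for comparing stem-cell-derived
    cardiomyocyte populations across six experimental modalities: action
    potential durations (APD30/APD80, cycle length) from voltage-dye optical
    mapping traces; Young's modulus from AFM approach curves via the
    spherical-tip Hertz model; dry-mass motion and percent mass fluctuation
    from quantitative phase microscopy time-lapses; single-cell RNA-seq
    quality control and two-group Wilcoxon marker detection; a
    transcription-factor promoter-occupancy enrichment simulation built on
    hypergeometric tests with Benjamini-Hochberg correction; and
    mitochondrial stress-test parameters from extracellular-flux oxygen
    consumption traces. Each stage is paired with a seeded synthetic-data
    generator carrying exact ground truth, so every estimator can be
    validated by recovery against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    tiff
Config/testthat/edition: 3
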