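Package: SynergyScreen
Title: Drug-Combination Synergy Scoring for Anchor Screens, Median-Effect
    Analysis, and Xenograft Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-drug combination experiments in cancer
    models: plate-reader viability normalization against vehicle controls,
    coefficient-of-drug-interaction (CDI) scoring and classification for
    high-throughput anchor screens with cross-model hit intersection,
    Chou-Talalay median-effect fitting with combination-index (CI) and
    dose-reduction-index (DRI) profiles for fixed-ratio designs, and in-vivo
    synergy scoring of xenograft tumor-growth trials with final-measure
    ANOVA/Tukey comparisons. A companion expression arm provides
    gene-signature scoring of Log2 TPM matrices, correlation-based
    hierarchical clustering and similarity summaries, MAD-based single-cell
    quality control, signature-restricted PCA, and antibody-array
    normalization. A simulation layer generates every input type with known
    ground truth (median-effect dose-response curves, Bliss/Loewe combination
    surfaces, anchor screens, exponential tumor-growth trials, expression
    cohorts, cell QC metrics) for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
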