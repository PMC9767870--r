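Package: gbmevolve
Title: Cohort-Level Single-Cell Analysis of Glioblastoma Evolution Under Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal single-cell analysis of glioblastoma
    cohorts profiled before and after standard therapy. Infers chromosome-arm
    copy-number variants from expression via two-component Gaussian mixture
    models and separates malignant from non-malignant cells; scores
    proneural/mesenchymal, cycling, monocytic activation (M0/M1/M2) and T-cell
    states with bin-matched control-gene module scores; computes transcription
    factor motif-accessibility deviations against background-matched peak
    sets, links enhancers to genes through meta-cell correlation and
    intersects the evidence into an AP1 regulome; and provides the paired
    cohort statistics (signed-rank, rank-sum, Fisher, hurdle-model likelihood
    ratio, Kaplan-Meier/log-rank, ligand-receptor scoring). Includes a
    synthetic paired-cohort generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
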