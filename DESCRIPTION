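Package: gal3fp
Title: Galectin-3 Interactome Fingerprinting and Molecular Subtyping of
    Transcriptomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reusable pipeline for stratifying bulk RNA-seq
    cohorts into molecular subgroups and scoring each sample against a
    galectin-3 (Gal-3) interactome fingerprint. Provides negative-binomial
    synthetic cohort and preclinical-design generators with ground truth;
    count-matrix input/output, median-of-ratios normalization, gene
    filtering, RIN binning and batch centering; consensus clustering
    (hierarchical Pearson-Ward, k-means, Gaussian mixture) with optimal
    label alignment and random-forest extension to held-out samples;
    bootstrap random-forest stability selection of a
    cluster-discriminating gene panel; composite up/down severity scores
    normalized against healthy volunteers; per-gene linear-model
    differential expression with fold-change and FDR calling;
    treatment-reversal analysis for preclinical designs; score-clinical
    association statistics; and a two-component PLS-DA for group
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    mclust,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
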