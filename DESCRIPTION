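Package: plasmapanel
Title: Plasma Proteomic Biomarker Panel Discovery with Synthetic Cohort
    Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for pooled-plasma SWATH-MS
    protein quantitation aimed at staged-disease biomarker discovery.
    Provides total-area normalization and replicate quality control for
    protein-by-run peak-area matrices; per-protein one-way ANOVA and
    pairwise t-tests with fold-change and trend-consistency filtering
    consolidated across depletion arms; classical multidimensional scaling
    and PCA of replicate and protein profiles; synthetic patient-cohort
    augmentation from pooled class centroids and technical-replicate
    standard deviations; shallow neural-network, k-nearest-neighbor and
    decision-tree stage classifiers evaluated on held-out synthetic and
    real pooled data; and greedy minimization of the candidate list to a
    compact panel that maintains classification accuracy. A seeded fixture
    generator emulates the statistical structure of pooled plasma
    experiments (abundance dynamic range, per-stage replicate CVs, planted
    fold changes, depletion-arm missingness) so the whole pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    nnet,
    vegan
Config/testthat/edition: 3
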