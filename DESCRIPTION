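Package: gamihc
Title: Quantification of Glioma-Associated Microglia/Macrophage
    Immunohistochemistry and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for brightfield immunohistochemistry quantification of
    glioma-associated microglia/macrophage (GAM) markers on tissue
    microarray (TMA) spots, and for the cohort- and expression-level
    statistics that accompany such studies.  Implements H-DAB colour
    deconvolution under the Beer-Lambert model, minimum cross-entropy
    (Li) and maximum-entropy (Kapur) histogram thresholding, a two-step
    DAB threshold refinement that is robust to varying background
    staining, and the DAB-area to tissue-area ratio per spot.  Cohort
    statistics cover first-core selection, necrosis-based exclusion,
    exact and approximate Wilcoxon rank-sum tests, Bonferroni-Holm
    adjustment, Spearman agreement, Kaplan-Meier estimation with
    log-rank and Gehan-Breslow-Wilcoxon tests, median-split and
    best-split marker dichotomization, and region-stratified analyses
    with Kruskal-Wallis and Dunn pairwise tests.  Expression utilities
    provide log2 fold-change screens, Ward clustering, Pearson
    coexpression, rank-product false-prediction estimates, delta-delta-Ct
    quantification and qPCR standard curves.  Seeded generators supply
    ground-truthed synthetic spots, survival cohorts and expression
    matrices so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
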