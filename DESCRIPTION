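Package: chaoscope
Title: Peripheral-Blood CD8+ T-Cell Subset, Repertoire and Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for profiling peripheral-blood CD8+ T cells from per-cell
    marker-intensity tables and paired-chain clonotype tables: automated
    CCR7/CD45RA/CD27/CD28 subset gating with per-donor frequency profiles and
    batch-normalised relative MFI; TCR-repertoire clonality (1 - Pielou
    evenness), Shannon diversity, clonal-expansion class decomposition and
    dual-chain VDJdb virus-specificity calls; gene-set module scoring with
    expression-matched control genes and healthy-relative scores; deterministic
    protein-marker pseudotime with patient-versus-healthy proportion
    differences; and evaluation of the preDN-Tem x preDP-Temra quadrant
    biomarker for immune-checkpoint-inhibitor response (binomial confidence
    intervals, Fisher exact tests, ROC AUC, Kaplan-Meier with the
    Gehan-Breslow-Wilcoxon test). A synthetic-cohort generator reproduces the
    statistical structure every stage assumes, so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    mclust,
    igraph,
    survival,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
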