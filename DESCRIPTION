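Package: orcoscreen
Title: Ligand-Based Virtual Screening and Assay Analytics for Orco Antagonist Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based virtual screening of insect odorant
    receptor co-receptor (Orco) antagonists. Implements Laplacian-corrected
    Naive Bayesian classification on sparse hashed circular (ECFP-style)
    fingerprints augmented with binned physicochemical descriptors, the
    EstPGood dual-Gaussian class probability, leave-one-out ROC validation,
    label-randomization null models, repeated stratified k-fold
    cross-validation, dual-model library ranking with EstPGood gating,
    Tanimoto diversity clustering with representative selection, structural
    novelty scoring, and the accompanying wet-lab analytics:
    percent-of-control inhibition with sham normalization, Hill
    concentration-inhibition (IC50) fitting, and the larval chemotaxis
    Response Index. Includes seeded synthetic-data generators for every
    pipeline input so the full screen is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
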