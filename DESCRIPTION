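Package: triomics
Title: Three-Generation Gut Multi-Omics Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale fecal multi-omics studies spanning
    family generations (infant, mother, grandmother). Implements pooled-QC
    batch strategies for untargeted GC-MS metabolomics: blank subtraction,
    presence and RSD quality-assurance filters, intra-batch drift correction
    by support-vector regression on QC injections (QC-SVRC), inter-batch
    QC-median scaling (QC-Norm), and KNN imputation. Provides chemometric
    models (PCA, NIPALS PLS-DA with cross-validated Q2), per-feature linear
    mixed models with family random intercepts and BH FDR control,
    metabolite-class ratios (SCFA/BCFA, MUFA/PUFA), community ecology
    summaries (richness, Shannon diversity, rank aggregation, minor-taxon
    lumping), TMM-normalized KEGG-Ortholog functional profiles with BRITE
    aggregation, Spearman taxa-metabolite association and hypergeometric
    pathway over-representation, and DIABLO-style multiblock sparse PLS-DA
    integration with repeated cross-validation, per-block AUROC, similarity
    networks and clustered image maps. A synthetic cohort generator with
    full ground truth (injection-order drift, batch offsets, family-correlated
    generation effects, Dirichlet-multinomial taxa, taxa-driven KO profiles)
    supports method validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    e1071,
    edgeR,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
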