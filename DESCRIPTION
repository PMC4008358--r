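Package: mirnapt
Title: Integrated miRNA-mRNA-Copy-Number Analysis of Breast Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrative pipeline for matched miRNA expression, gene
    expression and DNA copy-number profiles of breast tumours with clinical
    follow-up. Identifies copy-number-driven miRNAs (gain/loss
    stratification, Wilcoxon tests and dosage correlation), prognostic
    miRNAs (per-miRNA Cox proportional-hazards screening with
    Benjamini-Hochberg FDR, Kaplan-Meier tertile curves and multivariate
    covariate adjustment), intrinsic-subtype-specific miRNAs
    (nearest-centroid classification and per-miRNA ANOVA), miRNAs
    anti-correlated with their predicted targets (one-sided Fisher
    enrichment of anti-correlated candidate targets, "miRNAapt"), and the
    pathways and gene sets those miRNAs correlate with or transcriptionally
    influence (signature scoring, correlation clustering with bootstrap
    stability, targeted-set enrichment). Includes a synthetic multi-omics
    cohort generator with plantable ground truth so every stage can be
    exercised and validated without access to patient data.
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
    yaml,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
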