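Package: tvburden
Title: Tumor Variant and Neoepitope Burden Metrics for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes consensus tumor mutational burden (TMB) from multi-caller
    somatic variant calls with coverage adjustment, enumerates candidate
    neoepitope windows (8-24 aa) from protein-level variants, scores weighted
    neoepitope burdens (HLA allele presentation, amino-acid mismatch to the
    closest normal peptide, TCGA and patient-level transcript expression),
    identifies RNA-derived variant burdens (tumor-specific splice junctions
    against a normal compendium; retained introns via expression filters and a
    median-absolute-deviation outlier rule), and combines them into a tumor
    variant burden (TVB). Evaluates every burden metric as a predictor of
    immune checkpoint inhibitor response (ROC/AUC, logistic models with
    quartile response probabilities, Benjamini-Hochberg correction) and of
    overall survival (80th-percentile stratification, Cox proportional
    hazards, Kaplan-Meier, threshold sweeps), and quantifies cross-caller
    instability and threshold-dependent classification discordance. Ships a
    deterministic synthetic-cohort generator so the full pipeline is testable
    without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    survival,
    pROC,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
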