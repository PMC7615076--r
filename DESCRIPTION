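Package: glycomark
Title: Lectin-Pulldown Serum Glycoproteomics Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery-and-validation analysis pipeline for serum
    glycoprotein biomarkers measured by lectin-affinity pulldown mass
    spectrometry. Covers DDA-stage protein-group filtering,
    missingness-routed imputation (local least squares for sporadically
    missing features, minimum-value Gaussian draws for left-censored
    features), differential candidate shortlisting with overlap-aware
    summaries; MRM-stage transition aggregation, internal-standard
    coefficient-of-variation quality control and robust outlier flagging;
    peptide-level Benjamini-Hochberg differential testing with an
    all-peptides-consistent protein rule; and L1-penalized logistic
    multimarker panels evaluated by leave-one-out cross-validation with
    selection-frequency stability. A seeded synthetic-cohort generator
    with planted effects supports parameter-recovery testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
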