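Package: chemosig
Title: Targeted-Proteomics Signature Selection for Chemoresistance
    Classification in Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for deriving a protein biomarker
    signature of platinum chemoresistance in high-grade serous ovarian
    carcinoma from targeted proteomics data. Covers discovery-phase protein
    summarization (top-3 peptide averaging), equalized-median normalization,
    presence filtering and differential testing with multiple-testing
    correction; verification-phase parallel reaction monitoring (PRM)
    quantification with transition quality control, below-LOD background
    replacement, stable-isotope internal-standard normalization, technical CV
    reporting, best-peptide protein rollup and minimum-abundance imputation;
    repeated train/validation resampling with AUC-gain forward logistic
    selection and frequency-consensus model building; ROC analysis with
    DeLong confidence intervals, paired ROC comparison and Youden-optimal
    cutoffs; and a synthetic-data generator emulating the clinical and
    proteomic structure of a chemoresistant/chemosensitive cohort so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
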