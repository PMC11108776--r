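Package: dmmrtme
Title: Spatial Tumor-Microenvironment Biomarkers and Trial Endpoint
    Statistics for dMMR Gynecologic Cancer Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Correlative-analysis pipeline for single-arm phase 2
    immunotherapy trials in mismatch-repair-deficient gynecologic
    cancers. Quantifies spatial tumor-microenvironment biomarkers from
    segmented multiplexed-immunofluorescence cell tables (phenotype
    gating for dysfunctional CD8+PD-1+ and terminally dysfunctional
    CD8+PD-1+TOX+ T cells, nearest-neighbor distances, within-radius
    interaction fractions), derives trial endpoints (RECIST best overall
    response, ORR/DCR/PFS24 with exact Clopper-Pearson intervals,
    Kaplan-Meier summaries, exact Simon two-stage operating
    characteristics), runs group-association statistics (Mann-Whitney,
    Fisher exact, chi-square with PPV/NPV, tertile dichotomization,
    logistic model, ROC/AUC), and compares genomic profiles (tumor
    mutational burden, MSIsensor classification, mutational-signature
    labels, per-gene benefit scans). A synthetic cohort generator with
    known ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
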