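Package: petburden
Title: PERCIST Response Assessment and Metabolic Tumor Burden from PET Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies FDG-PET metabolic response from paired SUL
    (lean-body-mass normalized standardized uptake value) volumes:
    liver-background thresholds, 26-connected threshold-based lesion
    segmentation with SULmax/SULmean/MTV/TLG metrics, selection of up to
    five target lesions (at most two per organ), PERCIST 1.0 response
    categories, and summed tumor-burden change metrics. Includes a
    synthetic phantom and cohort generator with known ground truth, and
    the downstream outcome statistics: diagnostic accuracy, odds ratios,
    Mann-Whitney and chi-square comparisons, Kaplan-Meier and log-rank
    analysis with a median-outward optimal-cutoff search, Cox and
    logistic regression, ROC cutoffs and Spearman correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    RNifti,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
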