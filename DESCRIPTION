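Package: ssthet
Title: Whole-Body Somatostatin-Receptor PET Heterogeneity and Survival Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra- and inter-lesional heterogeneity of somatostatin
    receptor expression from whole-body PET standardized-uptake-value (SUV)
    volumes and relates the resulting patient-level imaging predictors to
    time-to-progression and overall survival. Provides a synthetic PET phantom
    and cohort generator with known ground truth, gradient-based star-convex
    lesion segmentation with a liver reference region, first-order
    intensity-histogram lesion features with a metabolic-volume eligibility
    filter, patient-level reductions including pairwise cosine-dissimilarity
    heterogeneity indices, and a survival stack: Kaplan-Meier estimation,
    univariable Cox screening with Uno's inverse-probability-of-censoring
    weighted C-statistic, LASSO-penalized Cox regression with repeated
    cross-validated penalty selection, and bootstrap optimism-corrected
    concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
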