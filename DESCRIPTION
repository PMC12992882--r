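Package: collrad
Title: Cerebrovascular Radiomics for Collateral Scoring on CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for objective collateral-status grading in
    acute large-vessel-occlusion stroke from CT angiography (CTA). Builds
    vessel-derived regions of interest from binary vessel-tree and circle of
    Willis segmentations, extracts shape, first-order and texture radiomics
    (including coif-1 wavelet and Laplacian-of-Gaussian filtered images),
    selects features by cross-validated importance with correlation pruning
    and incremental subset search, trains a tuned random-forest classifier of
    sufficient versus non-sufficient collaterals (dichotomized Tan score),
    and compares models with bootstrap confidence intervals and the DeLong
    test. Includes a synthetic cerebrovascular phantom generator so the whole
    pipeline can be exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ranger,
    glmnet,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
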