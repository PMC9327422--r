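Package: amlsig
Title: Sparse Multi-Omic Signatures of Ex Vivo Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts ex vivo drug sensitivity (dose-response AUC) of acute
    myeloid leukemia samples from multi-omic profiles (somatic mutations,
    transcript CPM, protein and phosphosite log-ratios). Provides drug
    panel filtering, penalized regression (lasso, elastic net, logistic)
    with nested cross-validation and held-out Spearman scoring, signature
    extraction, phosphosite-aware network contextualization via a
    randomized prize-collecting Steiner forest, hypergeometric
    over-representation analysis, and cell-line validation by hierarchical
    clustering. Includes a synthetic cohort generator with known ground
    truth for end-to-end testing of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
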