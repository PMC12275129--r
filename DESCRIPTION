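Package: neurohemo
Title: Multi-Modal Cerebrovascular MRI Analysis on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cerebrovascular mapping from
    multi-modal brain MRI: resting-state cerebrovascular reactivity (CVR)
    from BOLD coupling to the band-limited global signal, amplitude of
    low-frequency fluctuations (ALFF) and functional connectivity density
    (global, local and long-range FCD) from preprocessed BOLD, absolute
    cerebral blood flow from a one-compartment pseudo-continuous arterial
    spin labeling model, and arterial radius estimation from bright-vessel
    volumes via multiscale Hessian enhancement, region growing, centerline
    extraction and distance-transform sampling. Includes the full ROI-level
    statistical battery (Kruskal-Wallis with linear step-up FDR, rank-based
    post-hoc comparisons, Spearman and partial Spearman correlation,
    two-way random-effects ICC, Wilcoxon signed-rank, LASSO-logistic
    biomarker selection with ROC/AUC) and a synthetic phantom generator
    with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    pROC
VignetteBuilder: knitr
Config/testthat/edition: 3
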