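Package: faburden
Title: Lesion-Load Analysis of Skeletonized Fractional Anisotropy with
    Normative EZ Mapping and Prognostic Support-Vector Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level lesion-load analysis of skeletonized
    fractional-anisotropy (FA) maps. Builds a covariate-adjusted,
    bootstrap-stabilized normative model from healthy controls, converts
    subject FA maps into voxelwise EZ deviation maps, detects bidirectional
    (abnormally high and low FA) clusters with Gaussian-random-field or
    Monte-Carlo cluster-extent correction and ROC-optimized thresholds,
    cuts per-tract mean-FA cluster features, and trains and validates
    prognostic models of long-term cognitive outcome (linear SVM with
    recursive feature elimination, leave-one-out cross-validation,
    repeated subsampling, permutation testing, support-vector regression,
    serum-cytokine domain combination and frozen external validation).
    Includes a synthetic-cohort generator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
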