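Package: dbscompare
Title: Comparative Evaluation of Deep Brain Stimulation Activation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale framework for comparing computational models of
    deep brain stimulation (DBS) pathway activation. Implements parametric
    lead geometry for standard and segmented (directional) leads, a
    finite-difference quasi-static volume conductor with floating passive
    contacts and encapsulation-scar or tissue-class conductivities, two
    activation predictors (binary volume of tissue activated with
    structure-overlap and streamline-intersection metrics, and a
    driving-force predictor with per-fiber thresholds at nodes of Ranvier),
    native versus normative space machinery with synthetic deformation
    fields and lead re-straightening, a seeded synthetic cohort generator
    with zero-inflated evoked-potential amplitudes, and an evaluation
    harness (per-subject R-squared, paired Wilcoxon signed-rank tests,
    F-scores) comparing the six model variants crossing method, space
    and anatomical representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
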