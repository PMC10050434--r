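Package: modex
Title: Modality-Level Explanations for Multimodal Electrophysiology Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining 1-D convolutional sleep-stage classifiers
    trained on multimodal polysomnography (EEG, EOG, EMG). Provides a
    synthetic multimodal recording generator with planted modality importance
    and covariate effects, EDF/EDF+ ingest and 30-s epoching, a compact 1-D
    CNN with subject-wise cross-validated training, global ablation with
    zero-out and line-noise replacement, local per-sample ablation, layer-wise
    relevance propagation (epsilon and alpha-beta rules) with modality-level
    and time-resolved aggregation, and ordinary-least-squares analysis of
    local explanation magnitudes against age, sex, and medication with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
LinkingTo: Rcpp
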