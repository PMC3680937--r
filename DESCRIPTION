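Package: tnbcsynergy
Title: Cross-Species Signature Clustering, RNAi Screen Hit Calling, and
    Chou-Talalay Drug-Synergy Analysis for Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reimplements, as a tested pipeline with a synthetic-data
    module, the computational chain used to nominate a combination therapy
    for triple-negative breast cancer: projection of a transgenic-mouse
    tumor gene signature across species and platforms with hierarchical
    clustering under the uncentered-correlation distance, plate-based siRNA
    screen normalization with z-score hit calling and tumor-selectivity
    classification, and median-effect dose-response modelling with
    Chou-Talalay combination-index scoring of drug pairs. Synthetic
    generators emulate multi-dataset expression collections, 96-well screen
    plates, and single-agent and constant-interaction combination viability
    data so that every stage is exercisable without microarray or screen
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
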