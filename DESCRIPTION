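Package: stockgrid
Title: Uncertainty-Grid Validation of Age-Structured Stock Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale framework for validating integrated, age-structured
    fish stock assessments across a factorial uncertainty grid. A seeded
    operating model simulates catch, relative-abundance index and
    length-composition data with tuna-like biology; a catch-conditioned
    penalised maximum-likelihood estimator is fitted to each grid scenario;
    fits are scored with goodness-of-fit (runs test), retrospective (Mohn's
    rho), and hindcast prediction-skill (MASE, Diebold-Mariano) diagnostics;
    diagnostic pass/fail indicators weight scenarios into an ensemble that
    yields MSY reference points, Kobe phase classification with weighted risk
    probabilities, and a regression-tree analysis of factor importance.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
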