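Package: swapkit
Title: Swap-Error Analysis and Models for Cued Recall from Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying swap (non-target intrusion) errors in
    continuous-report cued recall tasks. Provides a circular-statistics core,
    a synthetic generator for cued-recall experiments with minimum-separation
    constraints, non-parametric and parametric swap-frequency estimators
    (nearest-item heuristic, three-component von Mises mixture fit by EM, and
    a corrected resultant-vector method), a parameter-free Monte Carlo
    predictor of swap rates from cue-dimension recall variability, and
    maximum-likelihood fitting with AIC/BIC comparison of a Poisson-spiking
    neural binding model (with conjunction-coding parameter) and full/partial
    interference models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
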