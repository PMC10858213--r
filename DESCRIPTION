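Package: alveofib
Title: Coupled Agent-Based and Dose-Deposition Simulation of
    Radiation-Induced Lung Fibrosis in an Alveolar Segment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of the onset of radiation-induced lung
    fibrosis (RILF) in a three-dimensional alveolar segment. The package
    builds an 18-alveoli segment lined by epithelial, mesenchymal and
    macrophage populations, produces per-cell absorbed doses from parametric
    samplers or a toy attenuation beam model, assigns initial cell fates with
    the linear-quadratic survival model, and evolves the tissue with an
    agent-based engine (senescence bystander spread, immune clearance,
    epithelial repopulation, mesenchymal expansion) coupled to an explicit
    FTCS reaction-diffusion solver for ten extracellular substances. Outcome
    statistics include the extracellular-matrix increase, functional-subunit
    survival, a fibrosis severity index, sigmoid/erf/critical-volume
    dose-response fits and a functional-subunit relative biological
    effectiveness for comparing radiation qualities and fractionation
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
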