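Package: bifactorirt
Title: Full-Information Bifactor Item Response Models for Mixed-Format Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marginal maximum likelihood calibration of full-information item
    bifactor (FIBF) models for tests mixing dichotomous two-parameter logistic
    items with graded (ordinal) items, together with their unidimensional
    (UIRT) and between-item multidimensional (MIRT) special cases. Estimation
    uses an EM algorithm with Gauss-Hermite quadrature and the bifactor
    dimension-reduction identity, supporting missing-by-design data from
    incomplete balanced block (linked booklet) test administrations. Includes
    expected a posteriori (EAP) ability scoring, AIC/BIC/SABIC/HQ model
    comparison, a linked-booklet test simulator, and Monte Carlo
    parameter-recovery and model-selection study drivers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, pracma, jsonlite, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
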