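Package: atriawave
Title: Spatial Calcium Wave Dynamics in Remodeled Atrial Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates centripetal calcium wave propagation in a spatially
    discretized rabbit atrial cardiomyocyte composed of 18 transversally
    coupled domains, with L-type calcium entry restricted to the two
    membrane domains and regenerative calcium-induced calcium release
    carrying the wave toward the cell center. Provides a calibrated
    population-of-models workflow, named tachypacing remodeling scenarios
    applied as multiplicative parameter scalings, per-beat action potential
    and calcium transient biomarkers, and a five-category classifier of
    calcium wave phenotypes (normal propagation, alternans, silencing,
    alternans with silencing, other). Includes a synthetic line-scan
    generator so the analysis layers are testable independently of the
    ordinary differential equation model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
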