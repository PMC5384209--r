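Package: fluxep
Title: Expectation Propagation for Metabolic Flux Polytopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic approximation of the marginal probability densities of
    metabolic fluxes constrained to the steady-state polytope S v = b with box
    bounds. Implements a Gaussian expectation-propagation (EP) scheme whose
    fixed-point marginals are truncated Gaussians, a non-adaptive Gaussian
    baseline, a constrained variant that pins a flux posterior to empirically
    measured moments, and the supporting machinery: model input/output (SBML,
    JSON, TSV), dead-end metabolite pruning, hit-and-run polytope sampling for
    validation, and flux balance analysis by linear programming. Results are
    returned as tidy tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
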