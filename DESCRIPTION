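Package: dcvax
Title: Multi-Level Kinetic Modeling of Dendritic-Cell Vaccination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a multi-level kinetic model of anti-cancer
    dendritic-cell (DC) vaccination: organ bio-distribution of intravenously
    injected DCs, NF-kB-driven DC maturation and cytokine production, and
    delayed DC-mediated CD8+ T-cell differentiation into effector and memory
    pools. Provides a calibrated reference parameterization, a synthetic
    time-series generator for the four calibration assays, staged hybrid
    parameter estimation (Latin hypercube sampling, pattern search, local
    gradient refinement), practical-identifiability diagnostics (estimate
    correlations and bootstrap confidence intervals), Sobol global sensitivity
    analysis of the memory T-cell output, and in-silico perturbation
    experiments that rank molecular targets for improving vaccine potency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    lhs,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
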