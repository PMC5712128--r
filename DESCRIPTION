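Package: growthtoggle
Title: Growth-Rate-Controlled Genetic Toggle Switch Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a genetic toggle switch whose balance
    is set by the bacterial growth rate through replication-dependent gene
    dosage. Provides Cooper-Helmstetter copy-number analytics for arbitrary
    chromosomal loci, a deterministic ODE approximation with quasi-static
    hysteresis scanning, an exact Gillespie-type lineage simulator with
    exponential cell growth, scheduled replication events and binomial
    partitioning at division, and estimators for protein-expression ratios,
    mean first passage (switching) times via exponential tail fitting,
    response times, and two-fold parameter sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
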