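Package: epistrat
Title: Multiscale Simulation of Epidermal Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional multiscale simulator of epidermal layer
    formation. Individual keratinocytes are represented with the subcellular
    element method (clusters of point elements coupled by spring and
    Lennard-Jones-type potentials with selective, cell-type-dependent
    adhesion), driven by a four-stage stem-cell lineage model (basal,
    proliferative spinous, mature spinous, granular) whose self-renewal,
    proliferation and differentiation rates are modulated by Ovol1/Ovol2
    transcription-factor levels and, optionally, by a diffusing calcium
    morphogen solved on a regular grid. The package provides the non-spatial
    lineage ODE model with genotype phenotype calls, four nested model
    variants (base, asymmetric division, selective adhesion, signal),
    stratification metrics (Sharpness Index, Isolation Ratio, per-slice
    Ripley's K), parameter sweeps with pattern classification, snapshot and
    event-log input/output, ggplot2 visualisations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
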