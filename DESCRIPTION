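Package: memnet
Title: Nonlinear Memory Functions for Subnetwork Reduction of Dynamical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces deterministic dynamical networks (gene regulatory circuits,
    mass-action systems) to an arbitrary subnetwork of tracked species. Starting
    from the quasi-steady-state (QSS) approximation for the eliminated "bulk"
    species, the package computes closed-form nonlinear memory functions that
    correct the reduced dynamics for the finite relaxation time of the bulk,
    in both a nonlinear (history-integral) and a self-consistent
    (auxiliary-ODE) form. Includes exact decomposition of the memory into
    interaction channels, channel ranking and ablation, fixed-point and
    basin-of-attraction analysis, oscillation classification and
    two-parameter Hopf-boundary scans, with tidy tabular outputs and ggplot2
    visualisations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
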