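Package: mirtrans
Title: Kinetic Modeling of microRNA Action on Protein Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of protein translation (the linear
    three-step cycle and the non-linear ribosome/initiation-factor recycling
    model of Nissan and Parker) together with their asymptotic analysis:
    steady states, the regime ratio beta separating efficient from
    inefficient initiation, staged dominant-system approximations of the
    transient dynamics, relaxation times, and qualitative kinetic signatures
    of microRNA mechanisms obtained from inhibition scans. Includes a small
    toolkit for linear multiscale reaction networks (exact eigen-solutions,
    chains, irreversible catalytic cycles with a limiting step,
    quasi-steady-state and quasiequilibrium reductions), SBML import/export
    of the two models, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    ggplot2,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
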