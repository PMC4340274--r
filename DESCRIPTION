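Package: grxkin
Title: Kinetic Modelling of Glutaredoxin Deglutathionylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of the glutaredoxin (Grx)
    deglutathionylation cycle: wild-type dithiol and active-site mutant core
    models, a glutathione-reductase-coupled system, and the HED
    (beta-hydroxyethyl disulphide) activity-assay model. Provides closed-form
    steady-state rate laws, a conservation-aware steady-state solver, double
    reciprocal (Lineweaver-Burk) plot analysis with ping-pong versus
    sequential line-family classification, Hill-equation fits of glutathione
    saturation curves, Levenberg-Marquardt estimation of rate constants from
    assay data, and a seeded synthetic-data generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
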