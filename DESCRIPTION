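Package: phratefit
Title: pH-Rate Profile Analysis of RNA Model Compound Cleavage Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for the transesterification
    kinetics of dinucleoside monophosphate RNA model compounds, including
    organometallic (arylmercury) catalysis. Implements the four-term pH-rate
    law for phosphodiester cleavage (hydronium-, water- and hydroxide-promoted
    background terms plus a catalytic term gated by a diprotic speciation
    equilibrium), exact matrix-exponential propagation of the first-order
    isomerization/cleavage/hydrolysis reaction network, extraction of observed
    cleavage and isomerization rate constants from mole-fraction time courses,
    nonlinear least-squares estimation of the rate and kinetic acidity
    constants from pH-rate profiles, weighted linear analysis of
    catalyst-concentration series, and a seeded synthetic-data generator that
    emulates HPLC time-course experiments so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
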