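Package: apopsynergy
Title: Mass-Action Modelling of TRAIL and LY303511 Apoptosis Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Ordinary-differential-equation models of TRAIL-induced
    extrinsic apoptosis in HeLa cells and of its sensitisation by the small
    molecule LY303511 (LY30). Provides a mass-action reaction-network
    representation with timed treatment events, Monte Carlo simulation of
    cell populations with variable initial protein levels and a
    cleaved-PARP death criterion, quantification of drug-combination
    synergy against the additive expectation, a reactive-oxygen-species
    model in which superoxide and hydrogen peroxide drive non-monotonic
    cFLIP regulation with scavenger-intervention predictions, multi-start
    parameter calibration, and generators for synthetic experimental
    readouts (caspase activity, cFLIP densitometry, viability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
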