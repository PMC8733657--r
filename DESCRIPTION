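Package: cefapbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modelling of
    Cefadroxil in Mouse, Rat, and Human
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Perfusion-limited whole-body physiologically based
    pharmacokinetic (PBPK) models of the cephalosporin antibiotic
    cefadroxil in mouse, rat, and human.  The systemic model couples 13
    well-stirred tissue compartments, lung, and arterial/venous blood
    pools through species-specific blood flows, with renal clearance as
    the sole elimination route.  Oral dosing in human is handled by a
    nine-segment compartmental absorption and transit gut model with
    first-order dissolution, passive permeation, and saturable
    PEPT1-mediated uptake distributed along the intestine according to
    measured segmental transporter expression.  The package also
    provides noncompartmental analysis, fold-error model qualification
    statistics (AFE/AAFE), clearance calibration, parameter sensitivity
    sweeps, allometric scaling, transporter-knockout and
    dissolution-rate experiments, and a synthetic observed-profile
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
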