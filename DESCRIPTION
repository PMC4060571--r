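Package: eaafes
Title: Equilibrium-Point Modelling and Identification for
    Agonist-Antagonist Functional Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling isometric elbow-joint hand-force control
    under two-channel functional electrical stimulation (FES) of an
    agonist-antagonist muscle pair. Implements the electrical
    agonist-antagonist (EAA) ratio and activity coding of co-contraction
    commands with per-subject stimulation-current calibration; generation
    of sinusoidal, composite, stepwise and burst stimulation protocols and
    the 60 Hz amplitude-modulated carrier; a second-order-plus-dead-time
    (SOPDT) plant model with analytic frequency response and exact
    discrete-time simulation; a synthetic virtual subject for end-to-end
    benchmarking; frequency-response system identification by steady-cycle
    harmonic regression and Bode fitting; and validation statistics for
    predicted versus measured hand force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
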