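Package: cochlearSNR
Title: Signal-to-Noise Enhancement by Distributed Wave Amplification in the Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how spatially distributed, cochlea-like wave
    amplification boosts signals more than spatially incoherent internal noise.
    Implements the closed-form cascaded noisy-amplifier chain (one-way and
    bidirectional), an active linear cochlear waveguide model with WKB and
    finite-difference solvers (1D transmission line and 2D box model),
    Monte-Carlo ensembles of incoherent sinusoidal noise sources, and
    narrowband/broadband signal-to-noise-ratio enhancement profiles along the
    cochlea, together with a reproducible pipeline for regenerating the
    figures and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
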