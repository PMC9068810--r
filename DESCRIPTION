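Package: hfqcompete
Title: Single-Molecule Analysis of Small RNA Competition for the Hfq Chaperone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-colour single-molecule TIRF
    competition experiments in which fluorophore-labelled small RNAs exchange
    on immobilized Hfq hexamers. Provides a stochastic event-driven simulator
    of resident/competitor kinetics rendered into noisy intensity traces or
    TIRF-like image stacks; spot detection, AOI filtering, channel mapping and
    intensity integration; trace segmentation into bound intervals with
    stoichiometry and flow-time change-point detection; per-molecule
    classification into passive competition, active displacement and stable
    coexistence; and censored multi-exponential dwell-time maximum-likelihood
    fitting with model selection, bootstrap errors and Kolmogorov-Smirnov
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
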