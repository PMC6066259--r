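Package: drgsoma
Title: Biophysical Simulation of the Urinary Bladder Small DRG Neuron Soma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based single-compartment simulation of the urinary
    bladder small dorsal root ganglion (DRG) neuron soma. Implements twenty-two
    plasma-membrane mechanisms (voltage-gated Na+, K+ and Ca2+ channels,
    Ca2+-activated K+ channels including an inwardly rectifying SK current,
    pumps and exchangers) together with a twelve-shell intracellular Ca2+
    system (rapid-buffer approximation, radial diffusion, PMCA, ER and
    mitochondrial fluxes, indicator-dye corrections). Provides protocol
    engines for current clamp, step and ramp voltage clamp, high-potassium
    challenge and conductance sweeps, plus analysis tools for action-potential
    and afterhyperpolarization features, I-V curves, Ca2+-transient features
    and a residual-standard-error goodness-of-fit statistic. Results are
    returned as tibbles for pipeline-style analysis and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    generics,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    arrow
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
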