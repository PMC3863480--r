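Package: columnhough
Title: Self-Structuring Cortical-Column Delay-Line Networks for
    Orientation-Selective Feature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cycle-accurate simulator of a feedforward spiking network in
    which parallel cortical columns of delay-line microcircuits learn, by a
    Boltzmann-annealed stochastic Hebbian rule on antagonistic direct/delay
    path weights, to map spatiotemporal binary patterns (bars of different
    slopes, discretized sinusoids) onto orientation-selective feature
    neurons - a neural realisation of a Hough transform. Includes
    spatiotemporal stimulus generators, a microelectrode-array stimulation
    protocol exporter, analytic and brute-force reference configurations,
    discrimination and truth-table evaluation, and perturbation tools
    (timing jitter, event dropout, column ablation) for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
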