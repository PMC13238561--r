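Package: eplsa
Title: Energy-Based Phase-Locking State Analysis of Brain Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies recurrent brain states from BOLD time series by
    combining instantaneous phase-locking analysis with pairwise
    maximum-entropy (Ising) energy landscapes. Network-averaged signals are
    Hilbert-transformed into instantaneous phases, per-frame phase-locking
    matrices are summarized by their sign-fixed leading eigenvectors and
    binarized into activity patterns, a pairwise maximum-entropy model is
    fitted by exact-gradient moment matching, and the resulting energy
    landscape is analysed for local minima, attraction basins,
    disconnectivity graphs, and basin-level state dynamics (fractional
    occupancy, dwell time, transition probabilities, direct versus indirect
    transitions). Includes leading-eigenvector clustering (LEiDA) and
    amplitude-based energy-landscape baselines, rank-based test-retest
    discriminability and symmetrized Kullback-Leibler evaluation statistics,
    and synthetic generators (exact Boltzmann samplers, Markov-switching
    phase-coupled oscillators, multi-subject reliability sets) for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
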