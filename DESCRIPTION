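Package: meiopair
Title: Agent-Based Simulation of Meiotic Homolog Pairing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the pairing of homologous chromosomes during meiotic
    prophase I as an ensemble of self-propelled chromosome centers of mass
    confined to a two-dimensional nuclear domain. Chromosomes move with a
    translational velocity, interact through short-range Morse (paired
    Yukawa) potentials that attract homologs and repel non-homologs, feel
    thermal noise and a repulsive nuclear envelope, and are captured
    permanently once homolog centers come within the pairing distance.
    Includes chromosome-size scaling of interaction radii, an active-dumbbell
    polymer variant, named scenario presets (chromosome-number, velocity,
    force-ablation and reduced-break mutant experiments), Monte-Carlo ensemble
    drivers, and tidy analysis of pairing fractions, distance kinetics,
    matched non-homolog controls and residence times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
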