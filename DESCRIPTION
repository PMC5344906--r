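Package: hbih
Title: Simulation and Chaos Analysis of a Thermoreceptor Bursting Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for the HB+Ih conductance-based
    neuron model, a Huber & Braun type cold-thermoreceptor burster extended
    with a hyperpolarization-activated current. Provides fixed-step
    Runge-Kutta integration with a compiled inner loop, spike detection and
    firing-pattern classification, maximal Lyapunov exponents of voltage
    trajectories (two-trajectory renormalization), Lyapunov exponents of
    inter-spike-interval series (delay embedding with nearest-neighbour
    stretching), Lempel-Ziv spike-train complexity, slow-subsystem equilibrium
    and bifurcation analysis (Hopf and limit-point detection, return-interval
    period-doubling counts) and reproducible parameter sweeps with tidy
    tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
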