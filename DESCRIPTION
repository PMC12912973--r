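Package: rodletkin
Title: Single-Fibril Kinetics and Lattice Simulation of Hydrophobin Rodlet Assembly
Version: 0.1.0
Authors@R:
    person("Rodletkin", "Developers", email = "rodletkin@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stop-and-go elongation kinetics of
    hydrophobin rodlets (class I functional amyloids) observed at the
    single-fibril level: a synthetic-data generator for two-state
    (growth/pause) end trajectories, precursor-height traces and
    thioflavin-T curves; dwell/step segmentation and exponential fitting of
    durations and step sizes; apparent elongation rates and the
    growth-pause equilibrium constant; rank-based (Brunner-Munzel) and
    paired permutation tests; integration and fitting of the dock-lock
    bulk elongation model; and a two-dimensional lattice Monte Carlo
    simulator of rodlet nucleation, elongation and lateral bundling with
    an orientational angle pair correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
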