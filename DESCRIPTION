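Package: nltaxis
Title: Nonlocal Diffusion-Taxis Models of Interacting Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of systems of N interacting populations
    that move by diffusion plus taxis up or down the gradient of a nonlocally
    averaged density of the other populations. Provides the non-dimensional
    model object and mappings from three mechanistic interaction scenarios
    (direct sensing, scent marking, spatial memory), linear pattern-formation
    analysis (dispersion relations, Turing versus wave instability, regime
    maps), a conservative finite-difference integrator on the periodic unit
    interval, energy-functional diagnostics for the symmetric two-population
    case, and a quasi-continuation bifurcation sweep that localises
    period-doubling transitions of oscillatory patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
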