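Package: osmoflow
Title: Mechanical Models of Osmotic Water Transport Across Semipermeable Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the mechanical (solute-membrane repulsion) theory of osmosis.
    Implements the phenomenological water-transport laws (van 't Hoff equilibrium,
    Darcy flow, the combined flux law, and the Pf/Pd permeability decomposition),
    continuum solute-concentration and pressure profiles across a semipermeable
    membrane at equilibrium and in the osmotic steady state (the Vegard pressure
    profile), overdamped Langevin (Brownian dynamics) simulation of ideal solute
    particles against a potential-barrier membrane, a pump-leak toy model of
    Donnan swelling and cell-volume stabilization, and the water/solute
    concentration arithmetic for dilute mixtures. Includes a fixture generator,
    a plain-text config schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
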