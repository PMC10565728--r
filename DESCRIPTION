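Package: evodyn
Title: Eco-Evolutionary Dynamics of Competing Species with Differing
    Evolvability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the coupled population and strategy dynamics of
    competing species that differ in evolvability, built on a
    fitness-generating (G-) function with Lotka-Volterra competition,
    Gaussian carrying-capacity and competition kernels, and a linear cost
    of evolvability.  Implements four environmental scenarios (clade
    initiation, evolutionary tracking under stochastic or sinusoidal
    drivers, evolutionary rescue after abrupt shifts, and adaptive
    radiation with evolutionary branching and speciation), adaptive
    landscape analysis, singular-strategy classification, and phylogeny
    output in Newick format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
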