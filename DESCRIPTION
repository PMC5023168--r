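Package: ddsnp
Title: Spiking Neural P Systems with Neuron Division and Dissolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exact, deterministic simulator for spiking neural P systems
    extended with neuron division and neuron dissolution (DDSN P systems), a
    membrane-computing model in which a directed graph of neurons exchanges
    spikes under firing, forgetting, division and dissolution rules guarded by
    semilinear spike-count sets.  Includes uniform constructions that solve
    SAT and Subset Sum in linearly many steps by generating an exponential
    workspace of output neurons and dissolving those that encode invalid
    solutions, brute-force oracles for cross-checking, step-complexity
    formulas for comparison with earlier spiking neural P system variants,
    DIMACS CNF input, JSON system specifications, JSON-lines traces and DOT
    export of configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
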