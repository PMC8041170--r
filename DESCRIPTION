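Package: quboasm
Title: Reference-Free DNA Assembly via QUBO, Simulated Annealing and QAOA
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Overlap-layout-consensus de novo assembly of error-free DNA
    reads, encoded as a directed traveling-salesman problem over the exact
    suffix-prefix overlap graph, reduced to a quadratic unconstrained binary
    optimization (QUBO) / Ising model, and solved three ways: exhaustive
    enumeration, seeded classical simulated annealing (a stand-in for a
    quantum annealer), and a QAOA variational loop on a dense statevector
    simulator. Ground states are decoded back into read orderings and
    stitched into an assembled sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
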