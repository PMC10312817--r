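Package: fibersync
Title: Fibration Symmetries and Cluster Synchronization in Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions small directed, weighted neuronal networks (such as the
    C. elegans locomotion sub-circuits) by graph fibration symmetries (fibers,
    via minimal balanced coloring and input trees) and by automorphism
    symmetries (orbits), decomposes them into fiber building blocks classified
    by fiber numbers (branching ratio and trail count), and verifies the
    predicted cluster synchronization by simulating admissible ODE models of
    gap-junction and chemical-synapse coupling, analysing their linear
    stability, and scoring synchrony with Gaussian-kernel (LoS) and
    phase-locking (PLV) metrics. Includes a synthetic-data generator that
    builds planted fibration lifts and locomotion-like left-right symmetric
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
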