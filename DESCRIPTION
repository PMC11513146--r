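Package: swrassembly
Title: Sharp-Wave Ripple and Cell-Assembly Analysis for Dual-Site
    Hippocampus-Amygdala Recordings
Version: 0.1.0
Authors@R:
    person("swrassembly", "maintainers", email = "swrassembly@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded dorsal CA1 and
    basolateral amygdala (BLA) units and local field potentials: detection of
    100-250 Hz sharp-wave ripples (offline and as a causal closed-loop
    simulation), extraction of co-activating cell assemblies by PCA eigenvalue
    counting against the Marchenko-Pastur bound followed by an ICA rotation,
    peri-ripple modulation statistics with ripple-modulation and
    memory-acquisition indices, a memory/non-memory ripple taxonomy with
    content and selectivity scores, lag-shifted Poisson GLM population
    decoding with shuffle controls, and place-cell spatial information
    scoring.  Includes a ground-truth synthetic session generator so every
    stage can be validated against planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
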