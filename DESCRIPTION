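Package: qpatent
Title: Quantum Search-Based Comparison of Markush Structure Patent Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact comparison of two pharmaceutical Markush-structure patent
    claims by Grover amplitude amplification on a built-in classical
    statevector simulator. Patent claims are expressed as finite grammars
    (an invariant core plus R-group production rules), enumerated claim
    compounds are encoded as computational basis states through a fixed-width
    SMILES symbol code table, and two patent-membership oracles are joined by
    phase kickback into an intersection oracle whose marked states are
    amplified and decoded back to compound notations. Includes Boolean
    minimization (Quine-McCluskey with shared-literal factoring) to compress
    marked-set oracles, a density-matrix noise engine with depolarizing,
    thermal-relaxation and readout channels for error-type scaling
    experiments, a coupling-graph routing-cost metric for qubit-mapping
    comparisons, OpenQASM 2.0 export, and a command-line interface with a
    seeded synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
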