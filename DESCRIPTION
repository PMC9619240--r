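Package: tadfscreen
Title: Evolutionary High-Throughput Virtual Screening of TADF Emitter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary engine for the computational design of thermally
    activated delayed fluorescence (TADF) emitters. Builds donor-acceptor
    compound libraries by combinatorial fragment enumeration, evolves them by
    selection and aromatic-site structural mutations (ring C-H to N swaps and
    terminal substitutions with F, CN, OMe or NMe2), screens each generation
    with a random-forest surrogate for the singlet-triplet gap trained on a
    small evaluated subset, and tracks library-level analytics: material
    abundance, aromatic C-H counts, Murcko skeleton convergence, group
    fingerprint similarity between libraries, an emission-color energy sieve,
    and final ranking of accumulated candidates by synthetic accessibility.
    Quantum-chemistry property engines are abstracted behind a pluggable
    contract; a deterministic structure-sensitive synthetic oracle is shipped
    for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
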