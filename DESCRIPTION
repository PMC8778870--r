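Package: fodm
Title: Fuzzy-Oil-Drop Hydrophobicity Analysis of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how closely the hydrophobicity distribution of a
    protein structure follows the micelle-like arrangement expected for a
    water-soluble globule, and how strongly a non-aqueous (membrane-like)
    environment has shaped it.  Given a PDB or mmCIF structure and a
    selection (complex, chain, domain set, individual domain, or fragment
    scored within its parent complex), the package computes the theoretical
    hydrophobicity profile T from a 3D Gaussian fitted to the molecule, the
    observed profile O from distance-damped pairwise hydrophobic
    interactions, the uniform reference R, and the environment-modified
    profile M(K) blending T with its complement.  Structures are scored by
    the relative distance RD, a ratio of Kullback-Leibler divergences, and
    by the environment-participation parameter K that minimises the
    divergence between O and M(K).  A synthetic-structure generator with
    known ground truth supports testing, and a command-line script exposes
    scoring, profiling and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
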