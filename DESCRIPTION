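Package: g4topo
Title: Topological Landscape and Foldability of G-Quadruplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enumerates the standard looping topologies of unimolecular
    G-quadruplexes from a strand-continuity walk over propeller, lateral
    and diagonal loop types, classifies propeller loops as short- or
    long-distance as a function of helicity, applies loop-length
    feasibility rules to rank candidate loop-length designs, and provides
    an RMSD-threshold foldability pipeline (idealised G-core scaffolds,
    Kabsch superposition, percentile thresholds, gradient-boosted
    foldability classification with exact coalition Shapley attribution)
    together with a synthetic-data generator that emulates the
    conformational grid used to map G-quadruplex foldability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
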