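Package: cascadeNE
Title: Network-Efficiency Estimation of Multi-Target Anticoagulant Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the human clotting cascade as a directed weighted graph and
    scores compounds by how much they reduce its network efficiency, the sum of
    reciprocal shortest-path lengths over ordered node pairs. Multi-target
    docking energies are transformed into edge "line values" that lengthen the
    out-edges of inhibited targets; compounds are ranked by the resulting drop
    in efficiency and validated against clotting-assay prolongation ratios
    (aPTT, PT, TT). Includes node and edge knockout fragility scans, a curated
    41-node clotting-cascade network, a two-stage hierarchical screening
    driver, drug-target network construction, and seed-deterministic synthetic
    generators for cascades, docking-score tables and assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
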