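Package: topomatch
Title: Secondary-Structure Topology Determination for Cryo-EM De Novo Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the topology (order and direction) that matches
    secondary-structure segments predicted on a protein sequence to
    secondary-structure sticks detected in a cryo-EM density volume.
    Builds a weighted directed layered graph over candidate assignments,
    finds the best-K valid topologies by dynamic programming with exact
    K-shortest-path enumeration, and scores graph edges with six schemes
    combining skeleton-trace fit, a bivariate-normal packing-geometry
    score, and a multi-well pairwise contact energy. Includes a synthetic
    fixture generator (toy helix bundles, rasterized loop skeletons,
    packing-angle samples) so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
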