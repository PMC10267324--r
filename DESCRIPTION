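Package: phyloutline
Title: Phylogenetic Consensus Outlines from Tree Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Summarises a profile of unrooted phylogenetic trees as a
    consensus outline: a greedy, PQ-tree-guided selection of a circular
    subset of the input splits, drawn as an outer-labeled planar polygon
    in which every split contributes exactly two parallel edges. Also
    provides strict, majority and greedy consensus trees, threshold
    consensus-network split selection, a weight-retention statistic that
    measures how much length-normalised split weight the chosen subset
    carries, Newick/Nexus input, SplitsTree-style Nexus SPLITS output and
    SVG rendering, plus seeded generators for conflict-bearing tree
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
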