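Package: mycelia
Title: Quantification of Growing Hyphal Networks from Whole-Field Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the development of a filamentous-fungus
    mycelium from time-lapse whole-field binary panoramas. The package
    extracts the centerline graph of the thallus (apexes, nodes, total
    hyphal length), corrects geometrical node counts for hyphal-overlap
    artifacts via a proximity criterion, fits exponential growth laws and
    decomposes them into branching and anastomosis rates, reconstructs
    intra-thallus areas (the enclosed faces of the planar network) and
    their fragmentation dynamics, and computes annulus/sector local
    statistics with Mann-Whitney reproducibility tests. A stochastic
    lattice-free 2-D mycelium growth simulator (exact birth-death counts
    plus a spatial tip-growth model with rendered panoramas) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    igraph,
    jsonlite,
    EBImage,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
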