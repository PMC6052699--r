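Package: flapsim
Title: Two-Tier Mass-Spring Skin Tissue Simulator for Local Flap Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless, scriptable simulator of basic skin surgery on a
    two-tier triangular-prism mass-spring lattice modelling layered skin
    (epidermis/dermis over fat). Supports pre-tensioned tissue, marking,
    vertical and horizontal (undermining) cuts with topological vertex
    duplication, excision and forceps removal of specimens, apposition
    testing with rigidified flap edges, and suturing with shrinking
    rest-length constraints, for three local-flap procedures: elliptical
    closure, bilateral advancement (H) flap and semicircular rotation
    flap. A staged state controller gates all interactions to plan
    vertices and replays scripted event streams deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
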