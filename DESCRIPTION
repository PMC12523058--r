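Package: veinsim
Title: Cell-Based Simulation of Auxin Canalization by PIN Transport and
    Plasmodesmata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the self-organization of leaf provascular strands
    from coupled intercellular auxin transport through polar PIN efflux
    carriers and through plasmodesmata (PD) whose aperture responds to
    auxin flux. Four coupled ODE families (cell auxin, wall PD area,
    cytoplasmic PIN, membrane PIN allocated up-the-gradient and
    with-the-flux) are integrated on polygonal cell tissues: square
    grids, irregular Voronoi leaves, imported VirtualLeaf-style XML
    geometries, and growing/dividing tissues. Includes scenario presets
    for transport-inhibitor (NPA) and plasmodesmata-aperture
    (cals3/gsl8) perturbations, patterning metrics (convergence points,
    strand extension and width, PD anisotropy), snapshot/metrics
    exporters and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'params.R'
    'tissue-geometry.R'
    'tissue-grid.R'
    'tissue-voronoi.R'
    'tissue-xml.R'
    'tissue-io.R'
    'dynamics.R'
    'growth.R'
    'metrics.R'
    'scenarios.R'
    'io.R'
    'cli.R'
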