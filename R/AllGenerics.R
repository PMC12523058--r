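#' @import methods
#' @importFrom stats runif
#' @importFrom Rcpp evalCpp
#' @useDynLib veinsim, .registration = TRUE
NULL

#' Number of cells in a tissue
#'
#' @param x A [Tissue-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Number of cell-cell walls in a tissue
#'
#' Only internal walls (interfaces between two cells) are counted; outline
#' segments between a cell and the outside carry no transport and are not
#' walls.
#'
#' @param x A [Tissue-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nWalls", function(x) standardGeneric("nWalls"))

#' Zone labels of all cells
#'
#' @param x A [Tissue-class] object.
#' @return Character vector, one of `"Z1"`, `"Z2"`, `"SINK"`,
#'   `"MARGIN_OTHER"`, `"INTERIOR"` per cell.
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))

#' Cell polygon areas
#'
#' @param x A [Tissue-class] object.
#' @return Numeric vector of positive areas in cell units squared.
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' Cell polygon centroids
#'
#' @param x A [Tissue-class] object.
#' @return Two-column numeric matrix (x, y), one row per cell.
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))

#' Adjacency list of the cell graph
#'
#' @param x A [Tissue-class] object.
#' @return List of integer vectors; element `i` holds the ids of the cells
#'   sharing a wall with cell `i`. Symmetric by construction.
#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))

#' Ordered margin (boundary) cell ids
#'
#' @param x A [Tissue-class] object.
#' @return Integer vector of cell ids tracing the tissue margin as a closed
#'   cycle.
#' @export
setGeneric("boundaryCells", function(x) standardGeneric("boundaryCells"))

#' Wall table of a tissue
#'
#' @param x A [Tissue-class] object.
#' @return A `data.frame` with columns `a`, `b` (cell ids, `a < b`) and
#'   `length` (summed length of the shared edge segments).
#' @export
setGeneric("walls", function(x) standardGeneric("walls"))

#' Per-cell auxin concentration of a simulation state
#'
#' @param x A [SimState-class] object.
#' @return Numeric vector (amount/cell), one entry per cell.
#' @export
setGeneric("auxin", function(x) standardGeneric("auxin"))

#' Per-cell auxin precursor level
#'
#' @param x A [SimState-class] object.
#' @return Numeric vector, one entry per cell.
#' @export
setGeneric("precursor", function(x) standardGeneric("precursor"))

#' Per-cell cytoplasmic PIN pool
#'
#' @param x A [SimState-class] object.
#' @return Numeric vector, one entry per cell.
#' @export
setGeneric("cytoPin", function(x) standardGeneric("cytoPin"))

#' Per-wall directed membrane PIN amounts
#'
#' @param x A [SimState-class] object.
#' @return Two-column numeric matrix; column `ab` is PIN in the membrane of
#'   wall cell `a` facing `b`, column `ba` the reverse side.
#' @export
setGeneric("membranePin", function(x) standardGeneric("membranePin"))

#' Per-wall total plasmodesmata cross-sectional area
#'
#' @param x A [SimState-class] object.
#' @return Numeric vector, one symmetric PD area per wall.
#' @export
setGeneric("pdArea", function(x) standardGeneric("pdArea"))

#' Per-wall net auxin flux frozen at the start of the last step
#'
#' @param x A [SimState-class] object.
#' @return Numeric signed vector; positive values flow from wall cell `a`
#'   to cell `b`.
#' @export
setGeneric("wallFluxes", function(x) standardGeneric("wallFluxes"))

#' Simulation time of a state
#'
#' @param x A [SimState-class] object.
#' @return Numeric scalar, computational seconds.
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' Snapshots of a simulation run
#'
#' @param x A [SimRun-class] object.
#' @return List of [SimState-class] snapshots.
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))

#' Snapshot times of a simulation run
#'
#' @param x A [SimRun-class] object.
#' @return Numeric vector of computational seconds, parallel to
#'   [snapshots()].
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))
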