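#' Zone labels understood by the tissue module
#'
#' `Z1` and `Z2` are marginal auxin-production zones (primary and secondary
#' vein initiation; Z2 activates later), `SINK` marks basal cells with
#' strong auxin decay standing in for the plant's existing vasculature,
#' `MARGIN_OTHER` is any other margin cell and `INTERIOR` everything else.
#'
#' @export
ZONE_LEVELS <- c("Z1", "Z2", "SINK", "MARGIN_OTHER", "INTERIOR")

#' Polygonal cell tissue
#'
#' A static or growing cell complex: polygonal cells over a shared node
#' set, with internal walls (cell-cell interfaces) carrying the transport
#' state. Construct via [makeSquareGrid()], [makeIrregularLeaf()] or
#' [importVirtualLeafXML()]; direct construction goes through the internal
#' `buildTissue()` which derives walls, adjacency and the margin cycle from
#' the node-indexed polygons.
#'
#' @slot nodes Two-column numeric matrix of node coordinates
#'   (dimensionless cell units; one unit is approximately one cell width).
#' @slot cellNodes List of integer vectors; each is a counter-clockwise
#'   simple polygon over rows of `nodes`.
#' @slot zone Character vector of [ZONE_LEVELS] labels, one per cell.
#' @slot birthArea Numeric vector; the area of each cell at its birth,
#'   used by the division rule.
#' @slot wallA,wallB Integer vectors of cell ids per wall, `wallA < wallB`.
#' @slot wallEdges List (one element per wall) of two-column integer
#'   matrices; each row is one shared node-pair segment of the interface.
#'   Several collinear or contiguous shared segments form a single wall.
#' @slot boundary Integer vector of margin cell ids, ordered as a closed
#'   cycle around the outline.
#' @slot geometryKind One of `"SQUARE_GRID"`, `"IRREGULAR_LEAF"`,
#'   `"IMPORTED"`.
#'
#' @seealso [nCells()], [nWalls()], [walls()], [zones()], [cellAreas()],
#'   [adjacencyList()], [boundaryCells()]
#' @export
setClass("Tissue", slots = c(
  nodes = "matrix",
  cellNodes = "list",
  zone = "character",
  birthArea = "numeric",
  wallA = "integer",
  wallB = "integer",
  wallEdges = "list",
  boundary = "integer",
  geometryKind = "character"
))

setValidity("Tissue", function(object) {
  n <- length(object@cellNodes)
  msgs <- character()
  if (length(object@zone) != n) msgs <- c(msgs, "one zone label per cell required")
  if (!all(object@zone %in% ZONE_LEVELS))
    msgs <- c(msgs, sprintf("unknown zone label(s): %s",
                            paste(setdiff(object@zone, ZONE_LEVELS), collapse = ", ")))
  if (length(object@birthArea) != n) msgs <- c(msgs, "one birthArea per cell required")
  nw <- length(object@wallA)
  if (length(object@wallB) != nw || length(object@wallEdges) != nw)
    msgs <- c(msgs, "wallA, wallB, wallEdges must have equal length")
  if (nw > 0) {
    if (any(object@wallA >= object@wallB))
      msgs <- c(msgs, "walls must be canonically oriented (a < b)")
    if (anyDuplicated(paste(object@wallA, object@wallB)))
      msgs <- c(msgs, "duplicated wall (unordered cell pair appears twice)")
    if (any(object@wallA < 1L) || any(object@wallB > n))
      msgs <- c(msgs, "wall cell ids out of range")
  }
  areas <- vapply(object@cellNodes, function(idx)
    polygonArea(object@nodes[idx, , drop = FALSE]), numeric(1))
  if (any(areas <= 0))
    msgs <- c(msgs, "all cell polygons must be counter-clockwise with positive area")
  special <- which(object@zone %in% c("Z1", "Z2", "SINK"))
  if (length(special) && !all(special %in% object@boundary))
    msgs <- c(msgs, "Z1/Z2/SINK cells must lie on the tissue boundary")
  if (length(msgs)) msgs else TRUE
})

#' Model parameters for the coupled PIN + plasmodesmata dynamics
#'
#' Holds every rate constant of the four ODE families plus scenario
#' switches. Defaults are the published reference parameterization of
#' normal (wild-type) vein patterning; see [pinpdParams()] for the
#' constructor and the meaning and units of each slot.
#'
#' @slot auxpr Auxin production rate constant (default 30).
#' @slot auxdec Auxin decay rate constant (0.5).
#' @slot Tpin PIN permeability constant T (6 normal; 2 / 1.5 graded NPA;
#'   0 with polar transport fully inhibited).
#' @slot Dperm PD permeability constant D (0.8).
#' @slot alpha Flux-dependent PD area increase rate (1e-4).
#' @slot beta Flux-independent PD area production rate (3e-2).
#' @slot gamma Flux-independent PD area decay rate (5e-2).
#' @slot kU Up-the-gradient PIN allocation rate (4e-3).
#' @slot kWl Linear with-the-flux PIN allocation rate (3e-3).
#' @slot kWq Quadratic with-the-flux PIN allocation rate (1e-5).
#' @slot kOff PIN membrane detachment rate (4e-3).
#' @slot pinpr Cytoplasmic PIN production constant (5e-3).
#' @slot pindec Cytoplasmic PIN decay constant (1e-2).
#' @slot cMargin Margin PIN efficiency C (0.833), a multiplier on `Tpin`
#'   whose placement is set by `cMarginPlacement`; inherited from the
#'   predecessor PIN-only model, where its exact placement is not
#'   restated.
#' @slot cMarginPlacement Where `cMargin` applies: `"off"` (default:
#'   the inherited constant's placement is not restated by the model
#'   sources, and either candidate placement distorts square-grid
#'   patterning - see the methods vignette), `"margin_margin"` (walls
#'   between two margin cells, damping the margin ring as a conduit) or
#'   `"producing_interior"` (walls joining an auxin-producing margin
#'   cell to an interior cell).
#' @slot fSat Saturation constant of the up-the-gradient response
#'   f(A) = fSat * A / (fSat + A) (100).
#' @slot auxdecSink Auxin decay rate in SINK cells (10; "strong" decay).
#' @slot aprecRamp Precursor ramp rate in active production zones
#'   (1e-4 per computational second).
#' @slot z1Init Initial Z1 precursor level (0.5; 2 in exogenous-auxin
#'   scenarios).
#' @slot z2Start Activation time of zone Z2 (9900 s = 2 h 45 m).
#' @slot timeScale Factor relating computational to biological time
#'   (10; reporting metadata only, never used by the dynamics).
#'
#' @export
setClass("PinPdParams", slots = c(
  auxpr = "numeric", auxdec = "numeric", Tpin = "numeric", Dperm = "numeric",
  alpha = "numeric", beta = "numeric", gamma = "numeric",
  kU = "numeric", kWl = "numeric", kWq = "numeric", kOff = "numeric",
  pinpr = "numeric", pindec = "numeric", cMargin = "numeric",
  cMarginPlacement = "character",
  fSat = "numeric", auxdecSink = "numeric", aprecRamp = "numeric",
  z1Init = "numeric", z2Start = "numeric", timeScale = "numeric"
))

setValidity("PinPdParams", function(object) {
  num <- setdiff(slotNames(object), "cMarginPlacement")
  vals <- vapply(num, function(s) slot(object, s), numeric(1))
  if (any(!is.finite(vals))) return("all parameters must be finite")
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0]
    return(sprintf("rate constants must be nonnegative: %s",
                   paste(bad, collapse = ", ")))
  }
  if (!object@cMarginPlacement %in% c("margin_margin", "producing_interior",
                                      "off"))
    return("cMarginPlacement must be 'margin_margin', 'producing_interior' or 'off'")
  TRUE
})

#' State of a tissue simulation at one instant
#'
#' Per-cell vectors hold intracellular auxin `A`, precursor `Aprec` and
#' cytoplasmic PIN `Pcyto`; per-wall vectors hold the symmetric PD area
#' `D`, the two directed membrane-PIN amounts `Pab`/`Pba` and the net
#' auxin flux `phi` frozen at the start of the most recent step (positive
#' from wall cell `a` toward `b`). All state variables are floored at
#' zero. Construct via [initState()].
#'
#' @slot t Computational time in seconds.
#' @slot A,Aprec,Pcyto Numeric per-cell vectors.
#' @slot D,Pab,Pba,phi Numeric per-wall vectors.
#' @export
setClass("SimState", slots = c(
  t = "numeric",
  A = "numeric", Aprec = "numeric", Pcyto = "numeric",
  D = "numeric", Pab = "numeric", Pba = "numeric", phi = "numeric"
))

setValidity("SimState", function(object) {
  nc <- length(object@A)
  nw <- length(object@D)
  if (length(object@Aprec) != nc || length(object@Pcyto) != nc)
    return("A, Aprec, Pcyto must have one entry per cell")
  if (length(object@Pab) != nw || length(object@Pba) != nw ||
      length(object@phi) != nw)
    return("D, Pab, Pba, phi must have one entry per wall")
  if (any(object@A < 0) || any(object@Pcyto < 0) || any(object@D < 0) ||
      any(object@Pab < 0) || any(object@Pba < 0))
    return("state variables must be nonnegative")
  TRUE
})

#' Growth and division parameters
#'
#' Zone-dependent relative growth rates (per computational hour, applied
#' to the birth area) and the area-doubling division rule.
#'
#' @slot G1 Growth rate of auxin-producing cells (precursor > 0; 0.2).
#' @slot G2 Growth rate of Z2 cells while their precursor is still zero
#'   (1.4).
#' @slot G3 Growth rate of all other cells (0.6).
#' @slot divisionRatio Area multiple of the birth area that triggers
#'   division (2: cells divide when they double in size).
#' @export
setClass("GrowthParams", slots = c(
  G1 = "numeric", G2 = "numeric", G3 = "numeric", divisionRatio = "numeric"
))

setValidity("GrowthParams", function(object) {
  if (any(c(object@G1, object@G2, object@G3) < 0)) return("growth rates must be >= 0")
  if (object@divisionRatio <= 1) return("divisionRatio must exceed 1")
  TRUE
})

#' A completed simulation run
#'
#' Returned by [runSimulation()] and [runScenario()]. Snapshots are full
#' [SimState-class] objects; for growing tissues the matching (possibly
#' divided) [Tissue-class] is stored per snapshot as well.
#'
#' @slot tissue Final [Tissue-class].
#' @slot params The [PinPdParams-class] used.
#' @slot times Numeric vector of snapshot times (computational seconds).
#' @slot states List of [SimState-class], parallel to `times`.
#' @slot tissues List of [Tissue-class], parallel to `times` (identical
#'   objects for non-growing runs).
#' @slot growth `NULL` or the [GrowthParams-class] used.
#' @export
setClass("SimRun", slots = c(
  tissue = "Tissue",
  params = "PinPdParams",
  times = "numeric",
  states = "list",
  tissues = "list",
  growth = "ANY"
))

#' Patterning metrics of one snapshot or run
#'
#' Quantifies the phenotypes read off simulated tissues: convergence
#' points (CPs) on the margin, strand extension toward the sink, strand
#' width, PD anisotropy and PIN polarity. See [metricsReport()].
#'
#' @slot cpCount Integer: number of detected CPs for the queried zone.
#' @slot cpCells Integer vector of CP cell ids.
#' @slot extensionFraction Progress of the farthest strand cell along the
#'   source-to-sink axis, in `[0, 1]`.
#' @slot reachedSink Logical: does the strand touch a sink-adjacent cell?
#' @slot timeToSink First snapshot time (s) at which the strand reached
#'   the sink, `NA` if never.
#' @slot strandWidth Mean number of strand cells per transverse band.
#' @slot pdAnisotropy Mean strand-internal PD area over mean
#'   strand-boundary PD area (1 = isotropic; `NA` for an empty strand).
#' @slot pinPolarity Mean absolute net PIN-carried flux per strand cell.
#' @export
setClass("MetricsReport", slots = c(
  cpCount = "integer", cpCells = "integer",
  extensionFraction = "numeric", reachedSink = "logical",
  timeToSink = "numeric", strandWidth = "numeric",
  pdAnisotropy = "numeric", pinPolarity = "numeric"
))

## ---- accessors ----

#' @rdname nCells
#' @export
setMethod("nCells", "Tissue", function(x) length(x@cellNodes))

#' @rdname nWalls
#' @export
setMethod("nWalls", "Tissue", function(x) length(x@wallA))

#' @rdname zones
#' @export
setMethod("zones", "Tissue", function(x) x@zone)

#' @rdname cellAreas
#' @export
setMethod("cellAreas", "Tissue", function(x)
  vapply(x@cellNodes, function(idx) polygonArea(x@nodes[idx, , drop = FALSE]),
         numeric(1)))

#' @rdname cellCentroids
#' @export
setMethod("cellCentroids", "Tissue", function(x) {
  m <- t(vapply(x@cellNodes, function(idx)
    polygonCentroid(x@nodes[idx, , drop = FALSE]), numeric(2)))
  colnames(m) <- c("x", "y")
  m
})

#' @rdname adjacencyList
#' @export
setMethod("adjacencyList", "Tissue", function(x) {
  adj <- vector("list", nCells(x))
  for (w in seq_along(x@wallA)) {
    a <- x@wallA[w]; b <- x@wallB[w]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) sort(unique(as.integer(v))))
})

#' @rdname boundaryCells
#' @export
setMethod("boundaryCells", "Tissue", function(x) x@boundary)

#' @rdname walls
#' @export
setMethod("walls", "Tissue", function(x) {
  data.frame(a = x@wallA, b = x@wallB, length = wallLengths(x))
})

#' @rdname auxin
#' @export
setMethod("auxin", "SimState", function(x) x@A)

#' @rdname precursor
#' @export
setMethod("precursor", "SimState", function(x) x@Aprec)

#' @rdname cytoPin
#' @export
setMethod("cytoPin", "SimState", function(x) x@Pcyto)

#' @rdname membranePin
#' @export
setMethod("membranePin", "SimState", function(x)
  cbind(ab = x@Pab, ba = x@Pba))

#' @rdname pdArea
#' @export
setMethod("pdArea", "SimState", function(x) x@D)

#' @rdname wallFluxes
#' @export
setMethod("wallFluxes", "SimState", function(x) x@phi)

#' @rdname simTime
#' @export
setMethod("simTime", "SimState", function(x) x@t)

#' @rdname snapshots
#' @export
setMethod("snapshots", "SimRun", function(x) x@states)

#' @rdname snapshotTimes
#' @export
setMethod("snapshotTimes", "SimRun", function(x) x@times)

## ---- show methods ----

setMethod("show", "Tissue", function(object) {
  zl <- table(factor(object@zone, levels = ZONE_LEVELS))
  cat(sprintf("Tissue (%s): %d cells, %d walls\n",
              object@geometryKind, nCells(object), nWalls(object)))
  cat("  zones:", paste(sprintf("%s=%d", names(zl), as.integer(zl)),
                        collapse = " "), "\n")
  ar <- cellAreas(object)
  cat(sprintf("  cell area: min %.3g, median %.3g, max %.3g\n",
              min(ar), stats::median(ar), max(ar)))
})

setMethod("show", "PinPdParams", function(object) {
  cat("PinPdParams (PIN + plasmodesmata auxin transport)\n")
  sn <- setdiff(slotNames(object), "cMarginPlacement")
  vals <- vapply(sn, function(s) slot(object, s), numeric(1))
  cat(paste(sprintf("  %-10s %g", sn, vals), collapse = "\n"), "\n")
  cat(sprintf("  cMarginPlacement %s\n", object@cMarginPlacement))
})

setMethod("show", "SimState", function(object) {
  cat(sprintf("SimState at t = %g s (%.2f h): %d cells, %d walls\n",
              object@t, object@t / 3600, length(object@A), length(object@D)))
  cat(sprintf("  auxin:  max %.4g, total %.4g\n", max(object@A, 0), sum(object@A)))
  cat(sprintf("  PD:     range [%.4g, %.4g]\n",
              min(object@D, Inf), max(object@D, -Inf)))
  cat(sprintf("  PIN:    cyto total %.4g, membrane total %.4g\n",
              sum(object@Pcyto), sum(object@Pab) + sum(object@Pba)))
})

setMethod("show", "SimRun", function(object) {
  cat(sprintf("SimRun: %d snapshots over t = [%g, %g] s, tissue of %d cells%s\n",
              length(object@times), min(object@times, Inf),
              max(object@times, -Inf), nCells(object@tissue),
              if (is.null(object@growth)) "" else " (growing)"))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  CPs: %d%s\n", object@cpCount,
              if (object@cpCount) paste0(" (cells ",
                paste(object@cpCells, collapse = ", "), ")") else ""))
  cat(sprintf("  extension: %.3f, reached sink: %s (t = %s s)\n",
              object@extensionFraction, object@reachedSink,
              if (is.na(object@timeToSink)) "never" else
                format(object@timeToSink)))
  cat(sprintf("  strand width: %.3g, PD anisotropy: %.3g, PIN polarity: %.3g\n",
              object@strandWidth, object@pdAnisotropy, object@pinPolarity))
})
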