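## Low-level polygon and tissue-assembly helpers. Coordinates are
## dimensionless cell units; conversion to micrometers (~9 um per cell
## width) happens only in reporting, never here.

#' Signed area of a polygon (positive when counter-clockwise)
#'
#' @param pts Two-column coordinate matrix of the polygon's vertices in
#'   order (not closed).
#' @return Numeric scalar, the shoelace signed area.
#' @keywords internal
polygonArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Centroid of a simple polygon
#' @param pts Two-column vertex matrix.
#' @return Numeric length-2 vector (x, y).
#' @keywords internal
polygonCentroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Point-in-polygon test (even-odd rule), vectorized over points
#' @param px,py Point coordinates.
#' @param poly Two-column vertex matrix.
#' @return Logical vector.
#' @keywords internal
pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Is a polygon simple (no self-intersections)?
#'
#' Brute-force segment pair test; adequate for the small polygons handled
#' here (tissue cells, outlines of a few dozen vertices).
#' @keywords internal
polygonIsSimple <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  seg <- cbind(pts, pts[c(2:n, 1), , drop = FALSE])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

#' Lengths of all walls of a tissue
#'
#' A wall's length is the summed length of its shared edge segments, so an
#' interface split by collinear intermediate nodes still reports its full
#' geometric length.
#'
#' @param tissue A [Tissue-class] object.
#' @return Numeric vector, one length per wall.
#' @export
wallLengths <- function(tissue) {
  vapply(tissue@wallEdges, function(e) {
    d <- tissue@nodes[e[, 2], , drop = FALSE] - tissue@nodes[e[, 1], , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}

## Assemble a Tissue from nodes + node-indexed polygons: derives walls
## (grouping contiguous shared edges per unordered cell pair), the ordered
## margin cycle, and default zone labels. The single constructor behind
## all tissue generators and the XML importer.
buildTissue <- function(nodes, cellNodes, zone = NULL, geometryKind = "IMPORTED",
                        birthArea = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  cellNodes <- lapply(cellNodes, as.integer)
  n <- length(cellNodes)

  ## orient counter-clockwise
  for (i in seq_len(n)) {
    pts <- nodes[cellNodes[[i]], , drop = FALSE]
    if (nrow(pts) < 3) stop(sprintf("cell %d has fewer than 3 vertices", i))
    if (polygonArea(pts) < 0) cellNodes[[i]] <- rev(cellNodes[[i]])
  }

  ## collect directed edges per cell; undirected key identifies sharing
  eCell <- integer(0); e1 <- integer(0); e2 <- integer(0)
  for (i in seq_len(n)) {
    idx <- cellNodes[[i]]
    nxt <- c(idx[-1], idx[1])
    eCell <- c(eCell, rep.int(i, length(idx)))
    e1 <- c(e1, idx); e2 <- c(e2, nxt)
  }
  key <- paste(pmin(e1, e2), pmax(e1, e2))
  tab <- table(key)
  if (any(tab > 2))
    stop("invalid geometry: an edge is shared by more than two cells")

  shared <- names(tab)[tab == 2]
  wallA <- integer(0); wallB <- integer(0); wallEdges <- list()
  if (length(shared)) {
    sidx <- which(key %in% shared)
    sidx <- sidx[order(key[sidx])]
    ## pairs of consecutive rows share a key
    k1 <- sidx[seq(1, length(sidx), by = 2)]
    k2 <- sidx[seq(2, length(sidx), by = 2)]
    ca <- pmin(eCell[k1], eCell[k2])
    cb <- pmax(eCell[k1], eCell[k2])
    if (any(ca == cb))
      stop("invalid geometry: a cell shares an edge with itself")
    pairKey <- paste(ca, cb)
    for (pk in unique(pairKey)) {
      rows <- which(pairKey == pk)
      wallA <- c(wallA, ca[rows[1]])
      wallB <- c(wallB, cb[rows[1]])
      wallEdges <- c(wallEdges,
                     list(cbind(e1[k1[rows]], e2[k1[rows]])))
    }
  }

  ## boundary: edges used by exactly one cell, walked as a node cycle
  bIdx <- which(key %in% names(tab)[tab == 1])
  boundary <- integer(0)
  if (length(bIdx)) {
    nxtNode <- new.env(hash = TRUE)
    edgeOwner <- new.env(hash = TRUE)
    for (r in bIdx) {
      assign(as.character(e1[r]), e2[r], envir = nxtNode)
      assign(paste(e1[r], e2[r]), eCell[r], envir = edgeOwner)
    }
    start <- e1[bIdx[1]]
    cur <- start
    ownSeq <- integer(0)
    for (step in seq_len(length(bIdx) + 1)) {
      nx <- get0(as.character(cur), envir = nxtNode)
      if (is.null(nx)) stop("boundary walk failed: open outline")
      ownSeq <- c(ownSeq, get(paste(cur, nx), envir = edgeOwner))
      cur <- nx
      if (cur == start) break
    }
    boundary <- ownSeq[c(TRUE, diff(ownSeq) != 0)]
    if (length(boundary) > 1 && boundary[1] == boundary[length(boundary)])
      boundary <- boundary[-length(boundary)]
  }

  if (is.null(zone)) {
    zone <- rep("INTERIOR", n)
    zone[boundary] <- "MARGIN_OTHER"
  }
  areas <- vapply(cellNodes, function(idx)
    polygonArea(nodes[idx, , drop = FALSE]), numeric(1))
  if (is.null(birthArea)) birthArea <- areas

  new("Tissue", nodes = nodes, cellNodes = cellNodes, zone = zone,
      birthArea = as.numeric(birthArea),
      wallA = as.integer(wallA), wallB = as.integer(wallB),
      wallEdges = wallEdges, boundary = as.integer(boundary),
      geometryKind = geometryKind)
}

## Validate and apply an explicit zone assignment (list with optional
## elements Z1, Z2, SINK of cell ids); all named cells must be on the
## boundary.
applyZoneSpec <- function(tissue, zoneSpec) {
  zone <- rep("INTERIOR", nCells(tissue))
  zone[tissue@boundary] <- "MARGIN_OTHER"
  for (zn in c("Z1", "Z2", "SINK")) {
    ids <- zoneSpec[[zn]]
    if (is.null(ids)) next
    ids <- as.integer(ids)
    off <- setdiff(ids, tissue@boundary)
    if (length(off))
      stop(sprintf("%s cells must be on the tissue boundary; cell(s) %s are not",
                   zn, paste(off, collapse = ", ")))
    zone[ids] <- zn
  }
  tissue@zone <- zone
  validObject(tissue)
  tissue
}

## Contiguous run of k boundary-cycle cells centered on position `at`
## (index into the cycle), as cell ids.
cycleRun <- function(cycle, at, k) {
  n <- length(cycle)
  offs <- seq_len(k) - 1L - (k - 1L) %/% 2L
  cycle[((at - 1L + offs) %% n) + 1L]
}

#' Assign leaf margin zones by position
#'
#' Labels distal margin cells (nearest the tip) Z1, one lateral group per
#' side at mid-height Z2, and basal margin cells SINK; every zone is a
#' contiguous run along the margin cycle. This is the default zone rule
#' for generated and imported leaves without explicit cell types.
#'
#' @param tissue A [Tissue-class] object with a non-empty boundary.
#' @param nZ1,nZ2,nSink Number of contiguous margin cells per zone
#'   (`nZ2` per side); defaults 3, 2, 3.
#' @param z2Height Fractional height (0 = base, 1 = tip) at which the
#'   lateral Z2 groups sit (default 0.6).
#' @return The tissue with zone labels replaced.
#' @export
assignLeafZones <- function(tissue, nZ1 = 3, nZ2 = 2, nSink = 3,
                            z2Height = 0.6) {
  cyc <- tissue@boundary
  if (!length(cyc)) stop("tissue has no boundary cells")
  cen <- cellCentroids(tissue)
  ys <- cen[cyc, 2]; xs <- cen[cyc, 1]
  tipAt <- which.max(ys); baseAt <- which.min(ys)
  z1 <- cycleRun(cyc, tipAt, nZ1)
  sink <- cycleRun(cyc, baseAt, nSink)
  yTarget <- min(ys) + z2Height * (max(ys) - min(ys))
  xc <- mean(range(xs))
  z2 <- integer(0)
  for (side in c(-1, 1)) {
    onSide <- which(sign(xs - xc) == side)
    onSide <- setdiff(onSide, c(tipAt, baseAt))
    if (!length(onSide)) next
    at <- onSide[which.min(abs(ys[onSide] - yTarget))]
    z2 <- c(z2, cycleRun(cyc, at, nZ2))
  }
  z2 <- setdiff(z2, c(z1, sink))
  applyZoneSpec(tissue, list(Z1 = z1, Z2 = z2, SINK = sink))
}
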