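## Clipped Voronoi tessellation with Lloyd relaxation. Implemented here
## directly (half-plane Sutherland-Hodgman clipping against bisectors)
## because the tissue needs conforming polygons with shared nodes, not
## just a point diagram.

#' Default leaf outline
#'
#' A vertically oriented, slightly tip-tapered oval: base at y = 0, tip
#' at y = `length`. Dimensions are in cell units, so the default outline
#' holds on the order of 180 cells of unit area with roughly 15-20 cells
#' between the distal margin and the base.
#'
#' @param length Base-to-tip extent (default 18).
#' @param width Maximal width (default 13).
#' @param n Number of outline vertices (default 48).
#' @return Two-column coordinate matrix (counter-clockwise, not closed).
#' @export
leafOutline <- function(length = 18, width = 13, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  s <- (1 - cos(th)) / 2                      # 0 at base, 1 at tip
  taper <- 1 - 0.25 * s                       # narrow toward the tip
  x <- (width / 2) * sin(th) * taper
  y <- length * s
  cbind(x, y)[order(th), , drop = FALSE]
}

## Clip a polygon against the half-plane {x : <x, nv> <= d}.
clipHalfPlane <- function(poly, nv, d) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  dots <- poly %*% nv
  keep <- dots <= d
  if (all(keep)) return(poly)
  if (!any(keep)) return(poly[0, , drop = FALSE])
  out <- matrix(0, n + 4, 2)
  m <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    pIn <- keep[k]; qIn <- keep[k2]
    if (pIn) { m <- m + 1L; out[m, ] <- poly[k, ] }
    if (pIn != qIn) {
      t <- (d - dots[k]) / (dots[k2] - dots[k])
      m <- m + 1L
      out[m, ] <- poly[k, ] + t * (poly[k2, ] - poly[k, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

## Voronoi cell of site i clipped to the outline. Sites are processed in
## order of increasing distance and clipping stops once no further site
## can cut the current polygon.
voronoiCell <- function(i, sites, outline) {
  p <- sites[i, ]
  d2 <- (sites[, 1] - p[1])^2 + (sites[, 2] - p[2])^2
  ord <- order(d2)
  ord <- ord[d2[ord] > 0]
  poly <- outline
  for (j in ord) {
    if (nrow(poly) < 3) break
    maxR2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    if (d2[j] > 4 * maxR2) break
    mid <- (p + sites[j, ]) / 2
    nv <- sites[j, ] - p
    poly <- clipHalfPlane(poly, nv, sum(mid * nv))
  }
  poly
}

## Merge vertices closer than `tol` into shared nodes (sweep + union-find).
mergeVertices <- function(verts, tol = 1e-6) {
  n <- nrow(verts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(verts[, 1], verts[, 2])
  for (ii in seq_len(n - 1)) {
    i <- ord[ii]
    for (jj in (ii + 1):n) {
      j <- ord[jj]
      if (verts[j, 1] - verts[i, 1] > tol) break
      if (abs(verts[j, 2] - verts[i, 2]) <= tol &&
          (verts[j, 1] - verts[i, 1])^2 + (verts[j, 2] - verts[i, 2])^2 <= tol^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  uroots <- sort(unique(roots))
  id <- match(roots, uroots)
  nodes <- matrix(0, length(uroots), 2)
  for (k in seq_along(uroots)) {
    rows <- which(roots == uroots[k])
    nodes[k, ] <- colMeans(verts[rows, , drop = FALSE])
  }
  list(nodes = nodes, id = id)
}

## Collapse polygon edges shorter than `minLen` to their midpoint.
## Voronoi diagrams of nearly cocircular sites produce arbitrarily short
## edges; those degenerate slivers destabilize growth relaxation and
## carry no meaningful wall, so they are removed at generation.
collapseShortEdges <- function(nodes, cellNodes, minLen = 0.05) {
  repeat {
    collapsed <- FALSE
    for (i in seq_along(cellNodes)) {
      idx <- cellNodes[[i]]
      m <- length(idx)
      if (m < 4) next
      nx <- c(idx[-1], idx[1])
      len <- sqrt(rowSums((nodes[nx, , drop = FALSE] -
                             nodes[idx, , drop = FALSE])^2))
      short <- which(len < minLen)
      if (!length(short)) next
      u <- min(idx[short[1]], nx[short[1]])
      v <- max(idx[short[1]], nx[short[1]])
      ## collapsing must not reduce any cell using the edge to a triangle
      usesEdge <- vapply(cellNodes, function(p) all(c(u, v) %in% p),
                         logical(1))
      if (any(usesEdge & lengths(cellNodes) < 4)) next
      nodes[u, ] <- (nodes[u, ] + nodes[v, ]) / 2
      cellNodes <- lapply(cellNodes, function(p) {
        p[p == v] <- u
        p <- p[c(TRUE, p[-1] != p[-length(p)])]
        if (length(p) > 1 && p[1] == p[length(p)]) p <- p[-length(p)]
        p
      })
      collapsed <- TRUE
      break
    }
    if (!collapsed) break
  }
  list(nodes = nodes, cellNodes = cellNodes)
}

#' Build an irregular Voronoi leaf tissue
#'
#' Seeds `nCells` sites uniformly inside a leaf outline, applies a few
#' Lloyd relaxation sweeps (sites moved to the centroids of their clipped
#' Voronoi cells) to obtain realistically irregular but non-degenerate
#' cells - areas vary roughly two-fold after relaxation - and assembles
#' the conforming polygonal tissue. Margin zones are assigned with
#' [assignLeafZones()]: distal cells Z1, lateral mid-leaf cells Z2 (both
#' sides), basal cells SINK. The same `(nCells, seed, outline)` always
#' yields the identical tissue.
#'
#' @param nCells Number of cells (>= 4).
#' @param seed Integer RNG seed for site placement.
#' @param outline Simple closed outline polygon as a two-column matrix
#'   (default [leafOutline()]). Self-intersecting outlines are rejected.
#' @param lloyd Number of Lloyd relaxation sweeps (default 4).
#' @param nZ1,nZ2,nSink Zone sizes passed to [assignLeafZones()].
#' @return A [Tissue-class] of kind `"IRREGULAR_LEAF"`.
#' @examples
#' tis <- makeIrregularLeaf(50, seed = 1)
#' range(cellAreas(tis))
#' @export
makeIrregularLeaf <- function(nCells, seed, outline = leafOutline(),
                              lloyd = 4, nZ1 = 3, nZ2 = 2, nSink = 3) {
  nCells <- as.integer(nCells)
  if (nCells < 4) stop("nCells must be >= 4")
  outline <- as.matrix(outline)
  if (!polygonIsSimple(outline)) stop("degenerate outline: self-intersecting")
  if (polygonArea(outline) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(as.integer(seed))

  bb <- apply(outline, 2, range)
  sites <- matrix(0, 0, 2)
  while (nrow(sites) < nCells) {
    m <- 2L * (nCells - nrow(sites)) + 8L
    px <- runif(m, bb[1, 1], bb[2, 1])
    py <- runif(m, bb[1, 2], bb[2, 2])
    ok <- pointsInPolygon(px, py, outline)
    sites <- rbind(sites, cbind(px[ok], py[ok]))
  }
  sites <- sites[seq_len(nCells), , drop = FALSE]

  for (iter in seq_len(lloyd)) {
    sites <- t(vapply(seq_len(nCells), function(i) {
      poly <- voronoiCell(i, sites, outline)
      if (nrow(poly) < 3) sites[i, ] else polygonCentroid(poly)
    }, numeric(2)))
  }

  polys <- lapply(seq_len(nCells), function(i) voronoiCell(i, sites, outline))
  nv <- vapply(polys, nrow, integer(1))
  if (any(nv < 3)) stop("degenerate Voronoi cell; try a different seed")
  verts <- do.call(rbind, polys)
  mg <- mergeVertices(verts)
  offs <- c(0L, cumsum(nv))
  cellNodes <- lapply(seq_len(nCells), function(i) {
    idx <- mg$id[(offs[i] + 1L):offs[i + 1L]]
    idx <- idx[c(TRUE, idx[-1] != idx[-length(idx)])]
    if (length(idx) > 1 && idx[1] == idx[length(idx)]) idx <- idx[-length(idx)]
    idx
  })
  cs <- collapseShortEdges(mg$nodes, cellNodes)
  tis <- buildTissue(cs$nodes, cs$cellNodes, geometryKind = "IRREGULAR_LEAF")
  assignLeafZones(tis, nZ1 = nZ1, nZ2 = nZ2, nSink = nSink)
}
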