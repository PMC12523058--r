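#' Construct growth parameters
#'
#' Zone-dependent relative growth rates. Rates are interpreted as the
#' fraction of the birth area added per computational hour; cells divide
#' on doubling their birth area.
#'
#' @param G1 Rate for auxin-producing cells, precursor > 0 (default 0.2).
#' @param G2 Rate for Z2 cells while their precursor is still 0 (1.4).
#' @param G3 Rate for all other cells (0.6).
#' @param divisionRatio Division threshold as a multiple of the birth
#'   area (2).
#' @return A [GrowthParams-class] object.
#' @export
growthParams <- function(G1 = 0.2, G2 = 1.4, G3 = 0.6, divisionRatio = 2) {
  new("GrowthParams", G1 = G1, G2 = G2, G3 = G3,
      divisionRatio = divisionRatio)
}

## Growth-rate class per cell: producing cells (precursor > 0) grow at
## G1, Z2 cells before activation at G2, everything else at G3.
growthRates <- function(tissue, state, growth) {
  g <- rep(growth@G3, nCells(tissue))
  g[tissue@zone == "Z2" & state@Aprec <= 0] <- growth@G2
  g[state@Aprec > 0] <- growth@G1
  g
}

#' Apply one growth step to a tissue
#'
#' Each cell's target area increases by its zone-class rate (fraction of
#' birth area per hour, see [growthParams()]); node positions then relax
#' toward the targets by a deterministic local scheme: every cell pushes
#' its nodes radially from its centroid by the square-root area mismatch
#' and nodes average the pushes of the cells sharing them. State
#' variables are amounts per cell and are carried unchanged (no
#' dilution).
#'
#' @param tissue A [Tissue-class] object.
#' @param state The matching [SimState-class] (read for zone activity,
#'   returned untouched apart from nothing - included for interface
#'   symmetry and future use).
#' @param dt Growth interval in computational seconds.
#' @param growth A [GrowthParams-class] object.
#' @param params A [PinPdParams-class] object (for the precursor-based
#'   rate classes).
#' @param relaxIter Relaxation sweeps per call (default 3).
#' @return List with elements `tissue` (moved nodes) and `state`
#'   (unchanged).
#' @export
growStep <- function(tissue, state, dt, growth, params, relaxIter = 3) {
  g <- growthRates(tissue, state, growth)
  if (all(g == 0)) return(list(tissue = tissue, state = state))
  target <- cellAreas(tissue) + g * tissue@birthArea * dt / 3600
  nd <- tissue@nodes
  for (it in seq_len(relaxIter)) {
    shift <- matrix(0, nrow(nd), 2)
    cnt <- numeric(nrow(nd))
    minEdge <- rep(Inf, nrow(nd))
    for (i in seq_len(nCells(tissue))) {
      idx <- tissue@cellNodes[[i]]
      pts <- nd[idx, , drop = FALSE]
      area <- polygonArea(pts)
      f <- sqrt(max(target[i], 1e-12) / max(area, 1e-12)) - 1
      cen <- polygonCentroid(pts)
      shift[idx, 1] <- shift[idx, 1] + f * (pts[, 1] - cen[1])
      shift[idx, 2] <- shift[idx, 2] + f * (pts[, 2] - cen[2])
      cnt[idx] <- cnt[idx] + 1
      nxt <- c(2:nrow(pts), 1)
      ev <- pts[nxt, , drop = FALSE] - pts
      elen <- sqrt(rowSums(ev^2))
      minEdge[idx] <- pmin(minEdge[idx], elen, c(elen[length(elen)],
                                                 elen[-length(elen)]))
      ## repel the endpoints of very short edges so slivers cannot
      ## collapse and fold under the area pushes
      short <- which(elen < 0.15 & elen > 1e-12)
      for (sE in short) {
        u <- ev[sE, ] / elen[sE] * (0.15 - elen[sE])
        shift[idx[sE], ] <- shift[idx[sE], ] - u
        shift[idx[nxt[sE]], ] <- shift[idx[nxt[sE]], ] + u
      }
    }
    mv <- which(cnt > 0)
    d <- 0.5 * shift[mv, , drop = FALSE] / cnt[mv]
    ## cap each node's move at a fraction of its shortest incident edge
    ## so relaxation cannot fold a polygon onto itself
    mag <- sqrt(rowSums(d^2))
    cap <- 0.2 * minEdge[mv]
    scale <- ifelse(mag > cap & mag > 0, cap / mag, 1)
    nd[mv, ] <- nd[mv, ] + d * scale
  }
  ## accept the largest damping of this event's movement that keeps
  ## every polygon simple; zero movement is the deterministic fallback
  allSimple <- function(nodes) {
    for (i in seq_len(nCells(tissue))) {
      if (!polygonIsSimple(nodes[tissue@cellNodes[[i]], , drop = FALSE]))
        return(i)
    }
    0L
  }
  old <- tissue@nodes
  accepted <- FALSE
  for (lambda in c(1, 0.5, 0.25, 0.125, 0.0625)) {
    cand <- old + lambda * (nd - old)
    if (allSimple(cand) == 0L) {
      tissue@nodes <- cand
      accepted <- TRUE
      break
    }
  }
  if (!accepted) {
    bad <- allSimple(old)
    if (bad > 0L)
      stop(sprintf("growth relaxation self-intersected cell %d", bad))
    ## keep the previous geometry for this event
  }
  list(tissue = tissue, state = state)
}

## Longest principal axis of a polygon's vertex cloud.
principalAxis <- function(pts) {
  cen <- colMeans(pts)
  m <- sweep(pts, 2, cen)
  ev <- eigen(crossprod(m) / nrow(m), symmetric = TRUE)
  ev$vectors[, 1]
}

#' Divide a cell if it has reached the division threshold
#'
#' A cell whose area reaches `divisionRatio` times its birth area is
#' split by a straight wall through its centroid perpendicular to the
#' polygon's longest principal axis (shortest-wall convention). Daughters
#' inherit the mother's per-cell state values (concentrations are
#' amounts/cell and are copied, not halved), her zone, and fresh birth
#' areas. The new shared wall starts at the flux-free PD level
#' `beta/gamma` with no membrane PIN; the mother's outer walls partition
#' their PD area and directed PIN length-proportionally between the
#' daughters. Divisions that would create a degenerate polygon leave the
#' cell intact.
#'
#' @param tissue A [Tissue-class] object.
#' @param state The matching [SimState-class].
#' @param cell Cell id to test.
#' @param growth A [GrowthParams-class] (threshold).
#' @param params A [PinPdParams-class] (new-wall PD level).
#' @return List with elements `tissue`, `state` and logical `divided`.
#' @export
maybeDivide <- function(tissue, state, cell, growth, params) {
  areas <- cellAreas(tissue)
  if (areas[cell] < growth@divisionRatio * tissue@birthArea[cell])
    return(list(tissue = tissue, state = state, divided = FALSE))
  divideCell(tissue, state, cell, params)
}

## Split `cell` through its centroid perpendicular to its longest axis.
divideCell <- function(tissue, state, cell, params) {
  nd <- tissue@nodes
  idx <- tissue@cellNodes[[cell]]
  pts <- nd[idx, , drop = FALSE]
  axis <- principalAxis(pts)
  cen <- polygonCentroid(pts)
  s <- (pts[, 1] - cen[1]) * axis[1] + (pts[, 2] - cen[2]) * axis[2]
  s[abs(s) < 1e-9] <- 1e-9  # nudge vertices off the cut line
  n <- length(idx)
  crossings <- which(s * s[c(2:n, 1)] < 0)
  if (length(crossings) != 2)
    return(list(tissue = tissue, state = state, divided = FALSE))

  ## insert the two cut nodes; remember which old edge each splits
  splitEdges <- list()
  newIds <- integer(2)
  for (k in 1:2) {
    e <- crossings[k]
    e2 <- if (e == n) 1L else e + 1L
    t <- s[e] / (s[e] - s[e2])
    p <- pts[e, ] + t * (pts[e2, ] - pts[e, ])
    nd <- rbind(nd, p)
    newIds[k] <- nrow(nd)
    splitEdges[[k]] <- c(idx[e], idx[e2])
  }

  insertNode <- function(path, n1, n2, newId) {
    m <- length(path)
    for (q in seq_len(m)) {
      q2 <- if (q == m) 1L else q + 1L
      if ((path[q] == n1 && path[q2] == n2) ||
          (path[q] == n2 && path[q2] == n1))
        return(append(path, newId, after = q))
    }
    path
  }

  cellNodes <- tissue@cellNodes
  ## conforming insertion into neighbors sharing the split edges
  for (k in 1:2) {
    for (j in seq_along(cellNodes)) {
      if (j == cell) next
      cellNodes[[j]] <- insertNode(cellNodes[[j]], splitEdges[[k]][1],
                                   splitEdges[[k]][2], newIds[k])
    }
  }
  ## augmented mother cycle with the cut nodes in place
  aug <- idx
  aug <- insertNode(aug, splitEdges[[1]][1], splitEdges[[1]][2], newIds[1])
  aug <- insertNode(aug, splitEdges[[2]][1], splitEdges[[2]][2], newIds[2])
  p1 <- match(newIds[1], aug); p2 <- match(newIds[2], aug)
  m <- length(aug)
  seg <- function(from, to) {
    if (from <= to) aug[from:to] else aug[c(from:m, 1:to)]
  }
  d1 <- seg(p1, p2)
  d2 <- seg(p2, p1)
  if (length(d1) < 3 || length(d2) < 3)
    return(list(tissue = tissue, state = state, divided = FALSE))

  nOld <- nCells(tissue)
  cellNodes[[cell]] <- d1
  cellNodes[[nOld + 1L]] <- d2

  ## edge-level provenance of the old walls, for partitioning wall state
  edgeKey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  oldWallOf <- new.env(hash = TRUE)
  oldLen <- wallLengths(tissue)
  for (w in seq_len(nWalls(tissue))) {
    e <- tissue@wallEdges[[w]]
    for (r in seq_len(nrow(e)))
      assign(edgeKey(e[r, 1], e[r, 2]), w, envir = oldWallOf)
  }
  ## edges split by the new nodes resolve to their parent edge
  parentEdge <- new.env(hash = TRUE)
  for (k in 1:2) {
    assign(edgeKey(splitEdges[[k]][1], newIds[k]),
           edgeKey(splitEdges[[k]][1], splitEdges[[k]][2]), envir = parentEdge)
    assign(edgeKey(newIds[k], splitEdges[[k]][2]),
           edgeKey(splitEdges[[k]][1], splitEdges[[k]][2]), envir = parentEdge)
  }

  zone <- c(tissue@zone, tissue@zone[cell])
  newTis <- buildTissue(nd, cellNodes, zone = NULL,
                        geometryKind = tissue@geometryKind)
  ## inherit zones; a special-zone daughter forced off the margin is
  ## demoted to keep the boundary invariant
  zone[!(seq_along(zone) %in% newTis@boundary) &
         zone %in% c("Z1", "Z2", "SINK")] <- "INTERIOR"
  zone[!(seq_along(zone) %in% newTis@boundary) & zone == "MARGIN_OTHER"] <-
    "INTERIOR"
  zone[(seq_along(zone) %in% newTis@boundary) & zone == "INTERIOR"] <-
    "MARGIN_OTHER"
  newTis@zone <- zone
  birth <- c(tissue@birthArea, 0)
  ar <- cellAreas(newTis)
  birth[cell] <- ar[cell]
  birth[nOld + 1L] <- ar[nOld + 1L]
  newTis@birthArea <- birth
  validObject(newTis)

  ## remap per-cell state
  oldCellOf <- function(i) if (i == nOld + 1L) cell else i
  newState <- new("SimState", t = state@t,
                  A = c(state@A, state@A[cell]),
                  Aprec = c(state@Aprec, state@Aprec[cell]),
                  Pcyto = c(state@Pcyto, state@Pcyto[cell]),
                  D = numeric(nWalls(newTis)), Pab = numeric(nWalls(newTis)),
                  Pba = numeric(nWalls(newTis)), phi = numeric(nWalls(newTis)))
  newState@Pcyto[cell] <- state@Pcyto[cell]

  bg <- pdSteadyState(params)
  for (w in seq_len(nWalls(newTis))) {
    x <- newTis@wallA[w]; y <- newTis@wallB[w]
    e <- newTis@wallEdges[[w]]
    Dacc <- 0; Pxy <- 0; Pyx <- 0; Phi <- 0; fresh <- 0
    for (r in seq_len(nrow(e))) {
      k <- edgeKey(e[r, 1], e[r, 2])
      pk <- get0(k, envir = parentEdge)
      if (!is.null(pk)) k <- pk
      ow <- get0(k, envir = oldWallOf)
      len <- sqrt(sum((nd[e[r, 2], ] - nd[e[r, 1], ])^2))
      if (is.null(ow)) { fresh <- fresh + len; next }
      frac <- len / oldLen[ow]
      Dacc <- Dacc + frac * state@D[ow]
      ## directed PIN follows the owning cell through the division
      oa <- tissue@wallA[ow]
      fwd <- oldCellOf(x) == oa
      Pxy <- Pxy + frac * (if (fwd) state@Pab[ow] else state@Pba[ow])
      Pyx <- Pyx + frac * (if (fwd) state@Pba[ow] else state@Pab[ow])
      Phi <- Phi + frac * (if (fwd) state@phi[ow] else -state@phi[ow])
    }
    if (fresh > 0) Dacc <- Dacc + bg  # the new division wall
    newState@D[w] <- Dacc
    newState@Pab[w] <- Pxy; newState@Pba[w] <- Pyx; newState@phi[w] <- Phi
  }
  list(tissue = newTis, state = newState, divided = TRUE)
}

## Divide every cell past threshold (one pass; newly created daughters
## are below threshold by construction).
divideReadyCells <- function(tissue, state, growth, params) {
  changed <- FALSE
  repeat {
    areas <- cellAreas(tissue)
    ready <- which(areas >= growth@divisionRatio * tissue@birthArea)
    if (!length(ready)) break
    res <- divideCell(tissue, state, ready[1], params)
    if (!res$divided) {
      ## undividable cell: bump its birth area so we do not loop on it
      tissue@birthArea[ready[1]] <- areas[ready[1]]
      next
    }
    tissue <- res$tissue; state <- res$state
    changed <- TRUE
  }
  list(tissue = tissue, state = state, changed = changed)
}
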