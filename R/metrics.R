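## Operational metrics for the patterning phenotypes read off simulated
## tissues: convergence points, strand membership, extension toward the
## sink, strand width, PD anisotropy, PIN polarity. Qualitative
## phenotypes ("poorer canalization", "extra CPs") are quantified through
## these definitions; the numeric rules are this package's
## operationalization, not published ones.

## PIN-carried part of the wall flux (signed, a to b).
pinFluxPerWall <- function(state, tissue, params) {
  prep <- prepareModel(tissue, params)
  fa <- state@A / (1 + state@A)
  prep$Tfac * (state@Pab * fa[prep$a] - state@Pba * fa[prep$b])
}

## Wall index for an unordered cell pair, NA if not adjacent.
wallIndexOf <- function(tissue, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  match(paste(a, b), paste(tissue@wallA, tissue@wallB))
}

#' Detect convergence points on the margin
#'
#' A convergence point (CP) is operationalized as a prominent local
#' maximum of auxin over the margin-cell cycle within a production
#' zone's neighborhood - the site where transport converges and a vein
#' initiates. Peaks are merged by prominence: a peak is absorbed into a
#' higher one when one of the margin arcs between them never dips more
#' than `mergeTol` (relative) below it. On near-symmetric tissues one
#' convergence site often shows two near-equal margin peaks around the
#' drained vein head (shallow dip: one CP), while genuinely split CPs
#' (exogenous auxin, reduced PIN transport) are separated by pronounced
#' dips and low-amplitude margin ripples are absorbed.
#'
#' @param state A [SimState-class] object.
#' @param tissue The matching [Tissue-class].
#' @param params The [PinPdParams-class] of the run (unused by the
#'   default rule but part of the metric interface).
#' @param zone Which production zone to scan (`"Z1"` or `"Z2"`).
#' @param reach Margin-cycle distance from the zone still counted as its
#'   neighborhood (default 3 cells).
#' @param mergeTol Relative auxin tolerance for merging adjacent
#'   near-equal margin cells into one CP (default 0.05).
#' @return Integer vector of CP cell ids (possibly empty; a uniform
#'   margin has no strict maximum and therefore no CP).
#' @export
detectCPs <- function(state, tissue, params, zone = "Z1", reach = 3,
                      mergeTol = 0.05) {
  cyc <- tissue@boundary
  nb <- length(cyc)
  if (nb < 3) return(integer(0))
  zPos <- which(tissue@zone[cyc] == zone)
  if (!length(zPos)) return(integer(0))
  cdist <- function(p, q) {
    d <- abs(p - q)
    pmin(d, nb - d)
  }
  inHood <- vapply(seq_len(nb), function(p)
    min(cdist(p, zPos)) <= reach, logical(1))
  A <- state@A[cyc]
  nxt <- c(2:nb, 1); prv <- c(nb, 1:(nb - 1))
  peaks <- which(A > 0 & A > A[prv] & A > A[nxt])
  if (!length(peaks)) return(integer(0))
  ## prominence merging: a peak joins a higher peak when one of the two
  ## margin arcs between them never dips more than mergeTol (relative)
  ## below the lower peak
  between <- function(p, q) {  # cycle positions strictly between p and q
    steps <- (q - p) %% nb
    if (steps <= 1) return(integer(0))
    ((p + seq_len(steps - 1) - 1) %% nb) + 1
  }
  arcMin <- function(p, q) {
    if (p == q) return(A[p])
    fwd <- between(p, q)
    bwd <- between(q, p)
    m1 <- if (length(fwd)) min(A[fwd]) else Inf
    m2 <- if (length(bwd)) min(A[bwd]) else Inf
    max(m1, m2)
  }
  ord <- peaks[order(-A[peaks], cyc[peaks])]
  kept <- integer(0)
  for (p in ord) {
    absorbed <- FALSE
    for (q in kept) {
      if (arcMin(p, q) >= (1 - mergeTol) * A[p]) { absorbed <- TRUE; break }
    }
    if (!absorbed) kept <- c(kept, p)
  }
  sort(cyc[kept[inHood[kept]]])
}

#' Cells belonging to the provascular strand
#'
#' Cells whose auxin reaches `theta` times the maximum over
#' non-source, non-sink cells, filtered to connected components that
#' touch a production zone (contain or neighbor a Z1/Z2 cell). Sink
#' cells are excluded throughout: they are a decay boundary condition
#' whose auxin load reflects inflow/decay balance, not patterning. An
#' all-zero auxin field yields an empty strand.
#'
#' @inheritParams detectCPs
#' @param theta Threshold fraction of the reference maximum
#'   (default 0.3).
#' @param sourceZones Zone labels treated as sources.
#' @return Sorted integer vector of strand cell ids.
#' @export
strandCells <- function(state, tissue, theta = 0.3,
                        sourceZones = c("Z1", "Z2")) {
  src <- tissue@zone %in% sourceZones
  sink <- tissue@zone == "SINK"
  ref <- !src & !sink
  nonSrcMax <- if (any(ref)) max(state@A[ref]) else max(state@A)
  if (!is.finite(nonSrcMax) || nonSrcMax <= 0) return(integer(0))
  cand <- which(state@A >= theta * nonSrcMax & !sink)
  if (!length(cand)) return(integer(0))
  keep <- tissue@wallA %in% cand & tissue@wallB %in% cand
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, as.vector(rbind(match(tissue@wallA[keep], cand),
                                              match(tissue@wallB[keep], cand))))
  comp <- igraph::components(g)$membership
  adj <- adjacencyList(tissue)
  touches <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    src[i] || any(src[adj[[i]]])
  }, logical(1))
  goodComp <- unique(comp[touches])
  sort(cand[comp %in% goodComp])
}

#' Number of distinct provascular strands
#'
#' Connected components of the strand cell set (see [strandCells()]);
#' each component is one source-connected strand. Multiple strands per
#' source zone are the hallmark of plasmodesmata-only patterning,
#' against the single convergence-point-rooted vein of the full model.
#'
#' @inheritParams strandCells
#' @return Integer component count (0 for an empty strand).
#' @export
countStrands <- function(state, tissue, theta = 0.3,
                         sourceZones = c("Z1", "Z2")) {
  s <- strandCells(state, tissue, theta, sourceZones)
  if (!length(s)) return(0L)
  keep <- tissue@wallA %in% s & tissue@wallB %in% s
  g <- igraph::make_empty_graph(n = length(s), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, as.vector(rbind(match(tissue@wallA[keep], s),
                                              match(tissue@wallB[keep], s))))
  igraph::components(g)$no
}

## Unit axis from the Z1 centroid to the sink centroid; returns function
## projecting points to normalized arc position in [0, 1].
sourceSinkAxis <- function(tissue) {
  cen <- cellCentroids(tissue)
  from <- colMeans(cen[tissue@zone == "Z1", , drop = FALSE])
  toCells <- if (any(tissue@zone == "SINK")) which(tissue@zone == "SINK")
             else which.min(cen[, 2])
  to <- colMeans(cen[toCells, , drop = FALSE])
  v <- to - from
  len <- sqrt(sum(v^2))
  if (len < 1e-12) return(function(p) rep(0, nrow(p)))
  u <- v / len
  function(p) pmin(pmax(((p[, 1] - from[1]) * u[1] +
                           (p[, 2] - from[2]) * u[2]) / len, 0), 1)
}

#' Strand extension and time-to-sink over a run
#'
#' For each snapshot, the extension fraction is the farthest strand
#' cell's normalized progress along the axis from the Z1 centroid to the
#' sink centroid; the sink is reached at the first snapshot whose strand
#' contains a cell adjacent to (or in) a SINK cell.
#'
#' @param run A [SimRun-class] object.
#' @param theta,sourceZones Passed to [strandCells()].
#' @return List with `series` (data.frame time, extension, reachedSink)
#'   and `timeToSink` (seconds, `NA` if never reached).
#' @export
extensionAndSink <- function(run, theta = 0.3,
                             sourceZones = c("Z1", "Z2")) {
  ext <- numeric(length(run@times))
  reach <- logical(length(run@times))
  for (k in seq_along(run@times)) {
    tis <- run@tissues[[k]]
    st <- run@states[[k]]
    strand <- strandCells(st, tis, theta, sourceZones)
    if (!length(strand)) next
    proj <- sourceSinkAxis(tis)
    ext[k] <- max(proj(cellCentroids(tis)[strand, , drop = FALSE]))
    adj <- adjacencyList(tis)
    sink <- tis@zone == "SINK"
    reach[k] <- any(vapply(strand, function(i)
      sink[i] || any(sink[adj[[i]]]), logical(1)))
  }
  list(series = data.frame(time = run@times, extension = ext,
                           reachedSink = reach),
       timeToSink = if (any(reach)) run@times[which(reach)[1]] else NA_real_)
}

#' Plasmodesmata anisotropy of a strand
#'
#' Mean PD area over strand-internal walls divided by mean PD area over
#' strand-boundary walls (walls with exactly one endpoint in the strand).
#' 1 means isotropic PD (e.g. any fresh state, where every wall sits at
#' `beta/gamma`); large values mean canalized, strand-aligned PD.
#'
#' @param state A [SimState-class] object.
#' @param tissue The matching [Tissue-class].
#' @param strand Integer cell ids from [strandCells()].
#' @return Numeric ratio, `NA` if undefined (empty strand, or no wall on
#'   one side of the comparison while PD areas differ).
#' @export
pdAnisotropy <- function(state, tissue, strand) {
  if (!length(strand)) return(NA_real_)
  inA <- tissue@wallA %in% strand
  inB <- tissue@wallB %in% strand
  int <- inA & inB
  bnd <- xor(inA, inB)
  if (!any(int) || !any(bnd)) {
    if (length(state@D) && diff(range(state@D)) <= 1e-12) return(1)
    return(NA_real_)
  }
  mean(state@D[int]) / mean(state@D[bnd])
}

#' Mean transverse width of a strand
#'
#' Strand cells are binned along the source-to-sink axis into bands one
#' typical cell diameter deep; the width is the mean strand-cell count
#' over nonempty bands.
#'
#' @inheritParams pdAnisotropy
#' @return Numeric width in cells (0 for an empty strand).
#' @export
strandWidth <- function(state, tissue, strand) {
  if (!length(strand)) return(0)
  proj <- sourceSinkAxis(tissue)
  cen <- cellCentroids(tissue)
  pos <- proj(cen[strand, , drop = FALSE])
  from <- colMeans(cen[tissue@zone == "Z1", , drop = FALSE])
  to <- colMeans(cen[tissue@zone == "SINK", , drop = FALSE])
  axLen <- sqrt(sum((to - from)^2))
  band <- sqrt(stats::median(cellAreas(tissue)))
  nb <- max(1L, ceiling(axLen / band))
  counts <- tabulate(pmin(floor(pos * nb) + 1L, nb), nb)
  mean(counts[counts > 0])
}

#' Mean absolute net PIN-carried flux over strand cells
#'
#' @inheritParams detectCPs
#' @param strand Integer cell ids.
#' @return Numeric scalar (0 for empty strand).
#' @export
pinPolarity <- function(state, tissue, params, strand) {
  if (!length(strand)) return(0)
  pf <- pinFluxPerWall(state, tissue, params)
  prep <- prepareModel(tissue, params)
  net <- as.numeric(prep$Minc %*% pf)
  mean(abs(net[strand]))
}

#' Full metrics report for a run
#'
#' Computes every patterning metric on the final snapshot plus the
#' time-resolved extension/time-to-sink over all snapshots.
#'
#' @param run A [SimRun-class] object.
#' @param zone Production zone scanned for CPs (default `"Z1"`).
#' @param theta Strand threshold (default 0.3).
#' @return A [MetricsReport-class] object.
#' @export
metricsReport <- function(run, zone = "Z1", theta = 0.3) {
  k <- length(run@states)
  st <- run@states[[k]]
  tis <- run@tissues[[k]]
  strand <- strandCells(st, tis, theta)
  cps <- detectCPs(st, tis, run@params, zone = zone)
  es <- extensionAndSink(run, theta)
  new("MetricsReport",
      cpCount = length(cps), cpCells = cps,
      extensionFraction = es$series$extension[k],
      reachedSink = es$series$reachedSink[k],
      timeToSink = es$timeToSink,
      strandWidth = strandWidth(st, tis, strand),
      pdAnisotropy = pdAnisotropy(st, tis, strand),
      pinPolarity = pinPolarity(st, tis, run@params, strand))
}
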