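#' Default zone assignment for square grids
#'
#' Places a contiguous Z1 production zone at the center of the distal
#' (top) row and a SINK at the center of the basal (bottom) row,
#' optionally a Z2 zone on each lateral column at mid-height. Square-grid
#' simulations are usually run with a single Z1 source, the less leaf-like
#' geometry making a multi-source vein network less meaningful.
#'
#' @param z1Width,sinkWidth Number of contiguous cells in Z1 / SINK
#'   (default 3).
#' @param z2Width Cells per lateral Z2 zone; 0 (default) for no Z2.
#' @return A function of `(nx, ny)` returning a list with elements `Z1`,
#'   `Z2`, `SINK` of cell ids, as expected by [makeSquareGrid()].
#' @export
gridZoneSpec <- function(z1Width = 3, sinkWidth = 3, z2Width = 0) {
  function(nx, ny) {
    cellId <- function(i, j) (j - 1L) * nx + i
    mid <- function(width, n) {
      width <- min(width, n)
      start <- (n - width) %/% 2L + 1L
      seq.int(start, length.out = width)
    }
    z2 <- integer(0)
    if (z2Width > 0 && ny > 2) {
      rows <- mid(z2Width, ny)
      z2 <- c(cellId(1L, rows), cellId(nx, rows))
    }
    list(Z1 = cellId(mid(z1Width, nx), ny),
         Z2 = z2,
         SINK = cellId(mid(sinkWidth, nx), 1L))
  }
}

#' Build a regular square-grid tissue
#'
#' `nx` by `ny` unit-square cells with walls between 4-neighbors; row 1 is
#' the base (sink end), row `ny` the distal tip. All cells have unit area.
#'
#' @param nx,ny Grid dimensions (cells per row / column), both >= 1.
#' @param zoneSpec Either a function of `(nx, ny)` returning a list with
#'   elements `Z1`, `Z2`, `SINK` of cell ids, or such a list directly;
#'   defaults to [gridZoneSpec()]. Ids naming non-boundary cells are
#'   rejected.
#' @return A [Tissue-class] of kind `"SQUARE_GRID"`.
#' @examples
#' tis <- makeSquareGrid(3, 3)
#' nCells(tis)  # 9
#' nWalls(tis)  # 12
#' @export
makeSquareGrid <- function(nx, ny, zoneSpec = gridZoneSpec()) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  nodeId <- function(i, j) (j - 1L) * (nx + 1L) + i  # i in 1..nx+1
  gx <- rep(0:nx, times = ny + 1L)
  gy <- rep(0:ny, each = nx + 1L)
  nodes <- cbind(as.numeric(gx), as.numeric(gy))
  cellNodes <- vector("list", nx * ny)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cellNodes[[(j - 1L) * nx + i]] <-
      c(nodeId(i, j), nodeId(i + 1L, j), nodeId(i + 1L, j + 1L), nodeId(i, j + 1L))
  }
  tis <- buildTissue(nodes, cellNodes, geometryKind = "SQUARE_GRID")
  if (is.function(zoneSpec)) zoneSpec <- zoneSpec(nx, ny)
  applyZoneSpec(tis, zoneSpec)
}
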