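#' Export tissue geometry as CSV tables
#'
#' Writes `cells.csv` (id, x, y, area, zone) and `walls.csv` (a, b,
#' length) into a directory.
#'
#' @param tissue A [Tissue-class] object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
exportTissueCSV <- function(tissue, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cen <- cellCentroids(tissue)
  utils::write.csv(
    data.frame(id = seq_len(nCells(tissue)), x = cen[, 1], y = cen[, 2],
               area = cellAreas(tissue), zone = zones(tissue)),
    file.path(dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(walls(tissue), file.path(dir, "walls.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Render a tissue snapshot as SVG
#'
#' Cells are filled green by auxin concentration (relative to the
#' snapshot maximum); walls are stroked blue by PD area and red by total
#' membrane PIN when a state is supplied. Intended for quick visual
#' inspection of patterning, not publication graphics.
#'
#' @param tissue A [Tissue-class] object.
#' @param path Output `.svg` file path.
#' @param state Optional [SimState-class] to color by.
#' @param scale Pixels per cell unit (default 24).
#' @return `path`, invisibly.
#' @export
tissueToSVG <- function(tissue, path, state = NULL, scale = 24) {
  nd <- tissue@nodes
  xr <- range(nd[, 1]); yr <- range(nd[, 2])
  w <- (diff(xr) + 2) * scale; h <- (diff(yr) + 2) * scale
  tx <- function(x) (x - xr[1] + 1) * scale
  ty <- function(y) h - (y - yr[1] + 1) * scale  # y up
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">', w, h))
  amax <- if (!is.null(state)) max(state@A, 1e-12) else 1
  zoneStroke <- c(Z1 = "#e6a800", Z2 = "#e6a800", SINK = "#666666",
                  MARGIN_OTHER = "#bbbbbb", INTERIOR = "#bbbbbb")
  for (i in seq_len(nCells(tissue))) {
    pts <- nd[tissue@cellNodes[[i]], , drop = FALSE]
    ptxt <- paste(sprintf("%.2f,%.2f", tx(pts[, 1]), ty(pts[, 2])),
                  collapse = " ")
    g <- if (is.null(state)) 0 else state@A[i] / amax
    fill <- sprintf("rgb(%d,%d,%d)", round(235 * (1 - g)), 235,
                    round(235 * (1 - g)))
    out <- c(out, sprintf(
      '<polygon points="%s" fill="%s" stroke="%s" stroke-width="1"/>',
      ptxt, fill, zoneStroke[[tissue@zone[i]]]))
  }
  if (!is.null(state) && nWalls(tissue) > 0) {
    dmax <- max(state@D, 1e-12)
    pmax_ <- max(state@Pab + state@Pba, 1e-12)
    for (wl in seq_len(nWalls(tissue))) {
      e <- tissue@wallEdges[[wl]]
      pd <- state@D[wl] / dmax
      pin <- (state@Pab[wl] + state@Pba[wl]) / pmax_
      col <- sprintf("rgb(%d,%d,%d)", round(255 * pin), 0, round(255 * pd))
      for (r in seq_len(nrow(e))) {
        out <- c(out, sprintf(
          '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="%.2f"/>',
          tx(nd[e[r, 1], 1]), ty(nd[e[r, 1], 2]),
          tx(nd[e[r, 2], 1]), ty(nd[e[r, 2], 2]), col,
          0.5 + 2.5 * max(pd, pin)))
      }
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
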