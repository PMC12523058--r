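#' Import a VirtualLeaf-style XML tissue geometry
#'
#' Reads the nodes/cells dialect used by VirtualLeaf geometry files: a
#' `<nodes>` block of `<node nr x y>` elements and a `<cells>` block
#' whose `<cell>` elements list their member nodes as `<node n="..."/>`
#' references. Node numbering in the file may start at 0 or 1. When every
#' cell carries a `cell_type` attribute naming a zone label (see
#' [ZONE_LEVELS]) those labels are used; otherwise margin cells are
#' labeled `MARGIN_OTHER` and `zoneRule` (if supplied) is applied.
#'
#' @param path Path to the XML file; a missing file is an I/O error.
#' @param zoneRule Optional function applied to the imported tissue to
#'   assign zones, e.g. [assignLeafZones].
#' @return A [Tissue-class] of kind `"IMPORTED"`.
#' @export
importVirtualLeafXML <- function(path, zoneRule = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot open geometry file: %s", path))
  doc <- xml2::read_xml(path)
  nodeEls <- xml2::xml_find_all(doc, ".//nodes/node")
  if (!length(nodeEls)) stop("no <nodes> found in geometry file")
  nr <- as.integer(xml2::xml_attr(nodeEls, "nr"))
  if (anyNA(nr)) nr <- seq_along(nodeEls) - 1L
  coords <- cbind(as.numeric(xml2::xml_attr(nodeEls, "x")),
                  as.numeric(xml2::xml_attr(nodeEls, "y")))
  if (anyNA(coords)) stop("node with missing x/y coordinate")
  lookup <- integer(max(nr) + 1L)
  lookup[nr + 1L] <- seq_along(nr)

  cellEls <- xml2::xml_find_all(doc, ".//cells/cell")
  ## VirtualLeaf files carry the outline as a <boundary_polygon>, which the
  ## xpath above excludes by requiring a <cells> parent.
  if (!length(cellEls)) stop("no <cells> found in geometry file")
  cellNodes <- vector("list", length(cellEls))
  for (i in seq_along(cellEls)) {
    refs <- as.integer(xml2::xml_attr(
      xml2::xml_find_all(cellEls[[i]], "./node"), "n"))
    bad <- refs[refs < 0 | refs > max(nr) | {
      idx <- lookup[pmax(refs, 0) + 1L]; idx == 0L
    }]
    if (anyNA(refs) || length(bad))
      stop(sprintf("cell %d references missing node(s): %s",
                   i, paste(unique(bad), collapse = ", ")))
    cellNodes[[i]] <- lookup[refs + 1L]
  }

  types <- xml2::xml_attr(cellEls, "cell_type")
  zone <- NULL
  if (!anyNA(types) && all(types %in% ZONE_LEVELS)) zone <- types
  tis <- buildTissue(coords, cellNodes, zone = zone, geometryKind = "IMPORTED")
  if (is.null(zone) && !is.null(zoneRule)) tis <- zoneRule(tis)
  tis
}

#' Export a tissue as VirtualLeaf-style XML
#'
#' Writes the same dialect [importVirtualLeafXML()] reads, including the
#' zone label as each cell's `cell_type`, so that a re-imported file
#' reproduces the topology and zones exactly.
#'
#' @param tissue A [Tissue-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportVirtualLeafXML <- function(tissue, path) {
  doc <- xml2::xml_new_root("leaf", name = "veinsim-export")
  nodesEl <- xml2::xml_add_child(doc, "nodes", n = nrow(tissue@nodes))
  for (i in seq_len(nrow(tissue@nodes))) {
    xml2::xml_add_child(nodesEl, "node", nr = i - 1L,
                        x = formatC(tissue@nodes[i, 1], digits = 15, format = "g"),
                        y = formatC(tissue@nodes[i, 2], digits = 15, format = "g"))
  }
  cellsEl <- xml2::xml_add_child(doc, "cells", n = nCells(tissue))
  for (i in seq_len(nCells(tissue))) {
    cEl <- xml2::xml_add_child(cellsEl, "cell", index = i - 1L,
                               cell_type = tissue@zone[i])
    for (nd in tissue@cellNodes[[i]])
      xml2::xml_add_child(cEl, "node", n = nd - 1L)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
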