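test_that("square grids have the expected cells, walls and areas", {
  t1 <- makeSquareGrid(1, 1)
  expect_equal(nCells(t1), 1)
  expect_equal(nWalls(t1), 0)

  t33 <- makeSquareGrid(3, 3)
  expect_equal(nCells(t33), 9)
  expect_equal(nWalls(t33), 12)  # 2 * 3 * (3 - 1), counted by brute force

  t44 <- makeSquareGrid(4, 4)
  expect_true(all(abs(cellAreas(t44) - 1) < 1e-12))

  ## brute-force wall count over several shapes
  for (dims in list(c(2, 2), c(5, 3), c(4, 7))) {
    nx <- dims[1]; ny <- dims[2]
    tis <- makeSquareGrid(nx, ny)
    expect_equal(nWalls(tis), nx * (ny - 1) + ny * (nx - 1))
    expect_equal(nCells(tis), nx * ny)
  }
})

test_that("grid zones sit on the boundary and bad zone specs are rejected", {
  tis <- makeSquareGrid(5, 5)
  zn <- zones(tis)
  special <- which(zn %in% c("Z1", "SINK"))
  expect_true(all(special %in% boundaryCells(tis)))
  expect_equal(sum(zn == "Z1"), 3)
  expect_equal(sum(zn == "SINK"), 3)
  ## cell 13 is the center of a 5x5 grid: not a boundary cell
  expect_error(makeSquareGrid(5, 5, zoneSpec = list(Z1 = 13, SINK = 1:3)),
               "boundary")
})

test_that("walls are canonical, unique, and adjacency is symmetric", {
  for (tis in list(makeSquareGrid(4, 5), makeIrregularLeaf(40, seed = 3))) {
    w <- walls(tis)
    expect_true(all(w$a < w$b))
    expect_equal(anyDuplicated(paste(w$a, w$b)), 0)
    adj <- adjacencyList(tis)
    for (i in seq_along(adj)) {
      for (j in adj[[i]]) expect_true(i %in% adj[[j]])
    }
    ## every wall's cells are mutually adjacent
    expect_true(all(mapply(function(a, b) b %in% adj[[a]], w$a, w$b)))
  }
})

test_that("irregular leaf generation is reproducible and well-formed", {
  l1 <- makeIrregularLeaf(50, seed = 11)
  l2 <- makeIrregularLeaf(50, seed = 11)
  expect_identical(l1@nodes, l2@nodes)
  expect_identical(l1@cellNodes, l2@cellNodes)

  outline <- leafOutline()
  cen <- cellCentroids(l1)
  expect_true(all(pointsInPolygon(cen[, 1], cen[, 2], outline)))
  ## all polygon vertices lie inside (or on) the outline bounding box
  expect_true(all(l1@nodes[, 1] >= min(outline[, 1]) - 1e-9 &
                    l1@nodes[, 1] <= max(outline[, 1]) + 1e-9))

  ar <- cellAreas(l1)
  expect_lt(max(ar) / min(ar), 4)

  zn <- zones(l1)
  expect_true(all(c("Z1", "Z2", "SINK") %in% zn))
  ## Z1 distal, sink basal
  expect_gt(mean(cen[zn == "Z1", 2]), mean(cen[zn == "SINK", 2]))

  ## self-intersecting outline is rejected
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(makeIrregularLeaf(10, seed = 1, outline = bowtie),
               "degenerate")
})

test_that("leaf generation seeds do not leak into the session RNG", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(makeIrregularLeaf(20, seed = 7))
  expect_identical(runif(3), expected)
})

test_that("VirtualLeaf XML import reads fixtures and round-trips", {
  path <- system.file("extdata", "twocell.xml", package = "veinsim")
  tis <- importVirtualLeafXML(path)
  expect_equal(nCells(tis), 2)
  expect_equal(nWalls(tis), 1)
  expect_equal(walls(tis)$length, 1)
  expect_equal(cellAreas(tis), c(1, 1))

  out <- file.path(tempdir(), "reexport.xml")
  exportVirtualLeafXML(tis, out)
  tis2 <- importVirtualLeafXML(out)
  expect_equal(nCells(tis2), nCells(tis))
  expect_equal(walls(tis2), walls(tis))
  expect_equal(zones(tis2), zones(tis))

  expect_error(importVirtualLeafXML(file.path(tempdir(), "nope.xml")),
               "cannot open")
})

test_that("collinear shared nodes form a single wall with summed length", {
  path <- system.file("extdata", "collinear.xml", package = "veinsim")
  tis <- importVirtualLeafXML(path)
  expect_equal(nCells(tis), 2)
  expect_equal(nWalls(tis), 1)
  expect_equal(walls(tis)$length, 2)  # two unit segments, one interface
})

test_that("XML import errors name the cell with missing node references", {
  bad <- file.path(tempdir(), "bad.xml")
  writeLines(c(
    '<leaf><nodes n="3">',
    '<node nr="0" x="0" y="0"/><node nr="1" x="1" y="0"/><node nr="2" x="0" y="1"/>',
    '</nodes><cells n="1">',
    '<cell index="0"><node n="0"/><node n="1"/><node n="9"/></cell>',
    '</cells></leaf>'), bad)
  expect_error(importVirtualLeafXML(bad), "cell 1")
})

test_that("tissue CSV export writes the documented tables", {
  tis <- makeSquareGrid(3, 3)
  dir <- file.path(tempdir(), "tiscsv")
  exportTissueCSV(tis, dir)
  cells <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells), 9)
  expect_named(cells, c("id", "x", "y", "area", "zone"))
  wallsTab <- read.csv(file.path(dir, "walls.csv"))
  expect_equal(nrow(wallsTab), 12)
})
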