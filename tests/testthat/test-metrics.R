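# Metrics are checked on crafted states where the expected value follows
# from the definition by hand.

gridWithZones <- function(nx = 7, ny = 5) {
  makeSquareGrid(nx, ny)
}

mkState <- function(tissue, A) {
  p <- pinpdParams()
  st <- initState(tissue, p)
  st@A <- A
  st
}

test_that("detectCPs finds crafted margin peaks and ignores uniform margins", {
  tis <- gridWithZones()
  p <- pinpdParams()
  cyc <- boundaryCells(tis)

  ## uniform auxin: no strict maximum, no CP
  st <- mkState(tis, rep(1, nCells(tis)))
  expect_length(detectCPs(st, tis, p), 0)

  ## single peak at the central Z1 cell
  z1 <- which(zones(tis) == "Z1")
  peak <- z1[2]
  A <- rep(0.1, nCells(tis)); A[peak] <- 2
  st <- mkState(tis, A)
  expect_equal(detectCPs(st, tis, p), peak)

  ## two separated peaks flanking the zone -> 2 CPs
  A <- rep(0.1, nCells(tis))
  A[z1[1]] <- 2; A[z1[3]] <- 2
  st <- mkState(tis, A)
  expect_equal(detectCPs(st, tis, p), sort(c(z1[1], z1[3])))

  ## adjacent near-equal cells merge into a single CP
  A <- rep(0.1, nCells(tis))
  A[z1[1]] <- 2; A[z1[2]] <- 1.98; A[z1[3]] <- 1.99
  st <- mkState(tis, A)
  expect_length(detectCPs(st, tis, p), 1)
})

test_that("strandCells thresholds and filters to source-connected components", {
  tis <- makeSquareGrid(5, 5)
  p <- pinpdParams()

  ## all zero -> empty strand
  st <- mkState(tis, rep(0, 25))
  expect_length(strandCells(st, tis), 0)

  ## a single high-auxin path from Z1 to the base: exactly that path
  cid <- function(i, j) (j - 1) * 5 + i
  path <- cid(3, 5:1)
  A <- rep(0, 25); A[path] <- 10
  st <- mkState(tis, A)
  ## center column minus the sink cell (sinks are excluded from strands)
  expect_equal(strandCells(st, tis), sort(setdiff(path, cid(3, 1))))

  ## a distant blob not connected to any source is filtered out
  A2 <- A; A2[cid(1, 1)] <- 10  # corner cell is SINK-adjacent but isolated
  st2 <- mkState(tis, A2)
  expect_equal(strandCells(st2, tis), strandCells(st, tis))

  ## theta = 0 keeps every source-connected cell
  expect_gt(length(strandCells(st, tis, theta = 0)), length(path))
})

test_that("extension and time-to-sink follow the crafted snapshots", {
  tis <- makeSquareGrid(5, 9)
  p <- pinpdParams()
  cid <- function(i, j) (j - 1) * 5 + i

  emptyRun <- new("SimRun", tissue = tis, params = p, times = 0,
                  states = list(mkState(tis, rep(0, 45))),
                  tissues = list(tis), growth = NULL)
  es <- extensionAndSink(emptyRun)
  expect_equal(es$series$extension, 0)
  expect_true(is.na(es$timeToSink))

  ## strand spanning the upper half of the axis -> extension ~ 0.5
  A <- rep(0, 45); A[cid(3, 9:5)] <- 10
  half <- new("SimRun", tissue = tis, params = p, times = 0,
              states = list(mkState(tis, A)), tissues = list(tis),
              growth = NULL)
  expect_equal(extensionAndSink(half)$series$extension, 0.5,
               tolerance = 0.07)

  ## full column: reaches the sink-adjacent row
  A2 <- rep(0, 45); A2[cid(3, 9:2)] <- 10
  states <- list(mkState(tis, A), mkState(tis, A2))
  run <- new("SimRun", tissue = tis, params = p, times = c(100, 200),
             states = states, tissues = list(tis, tis), growth = NULL)
  es2 <- extensionAndSink(run)
  expect_equal(es2$timeToSink, 200)
  expect_false(es2$series$reachedSink[1])
})

test_that("pdAnisotropy matches arithmetic and the isotropic contracts", {
  tis <- makeSquareGrid(5, 5)
  p <- pinpdParams()
  st <- initState(tis, p)
  cid <- function(i, j) (j - 1) * 5 + i
  strand <- cid(3, 1:5)

  ## fresh state: every wall at beta/gamma -> exactly 1
  expect_equal(pdAnisotropy(st, tis, strand), 1)
  ## empty strand undefined
  expect_true(is.na(pdAnisotropy(st, tis, integer(0))))

  ## crafted: internal walls at 1.2, boundary walls at 0.3 -> 4.0
  w <- walls(tis)
  internal <- w$a %in% strand & w$b %in% strand
  boundary <- xor(w$a %in% strand, w$b %in% strand)
  st@D[internal] <- 1.2
  st@D[boundary] <- 0.3
  expect_equal(pdAnisotropy(st, tis, strand), 4)
})

test_that("strandWidth counts cells per transverse band", {
  tis <- makeSquareGrid(7, 7)
  cid <- function(i, j) (j - 1) * 7 + i
  p <- pinpdParams()
  st <- initState(tis, p)
  ## a 1-cell-wide column: 7 cells over 6 axis bands (the band at the
  ## sink end collects the clamped last cell) -> mean 7/6
  expect_equal(strandWidth(st, tis, cid(4, 1:7)), 7 / 6)
  ## a 3-cell-wide band: 3 cells per band, doubled in the last -> 3.5
  wide <- c(cid(3, 1:7), cid(4, 1:7), cid(5, 1:7))
  expect_equal(strandWidth(st, tis, wide), 3.5)
  expect_equal(strandWidth(st, tis, integer(0)), 0)
})

test_that("metricsReport assembles a consistent report from a short run", {
  tis <- makeSquareGrid(7, 7)
  p <- resolveScenario("PIN_PAT_I")
  run <- runSimulation(tis, p, tEnd = 1800, dt = 1,
                       snapshotTimes = c(0, 900, 1800))
  m <- metricsReport(run)
  expect_s4_class(m, "MetricsReport")
  expect_equal(m@cpCount, length(m@cpCells))
  expect_gte(m@extensionFraction, 0)
  expect_lte(m@extensionFraction, 1)
  expect_output(show(m), "MetricsReport")
})
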