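# The dynamics are checked at three levels: hand-computed values for the
# individual rate functions, an independent straight-line transcription
# of the four equations (helper-oracle.R), and closed-form solutions of
# reduced systems.

twoCellTissue <- function() {
  importVirtualLeafXML(system.file("extdata", "twocell.xml",
                                   package = "veinsim"))
}

test_that("parameter defaults and analytic identities match the model tables", {
  p <- pinpdParams()
  expect_equal(p@auxpr, 30)
  expect_equal(p@auxdec, 0.5)
  expect_equal(p@Tpin, 6)
  expect_equal(p@Dperm, 0.8)
  expect_equal(p@alpha, 1e-4)
  expect_equal(p@beta, 3e-2)
  expect_equal(p@gamma, 5e-2)
  expect_equal(p@kU, 4e-3)
  expect_equal(p@kWl, 3e-3)
  expect_equal(p@kWq, 1e-5)
  expect_equal(p@kOff, 4e-3)
  expect_equal(p@pinpr, 5e-3)
  expect_equal(p@pindec, 1e-2)
  expect_equal(p@cMargin, 0.833)
  expect_equal(pdSteadyState(p), 0.6)
  expect_equal(backgroundWallPermeability(p), 0.48)
  expect_error(pinpdParams(auxdec = -1), "nonnegative")
  expect_error(overrideParams(p, list(nosuch = 1)), "unknown parameter")
})

test_that("wallFlux reproduces hand-computed values and is antisymmetric", {
  tis <- twoCellTissue()
  p <- pinpdParams(cMarginPlacement = "off")
  st <- initState(tis, p)

  ## no gradient, no PIN
  st@A <- c(1, 1); st@Pab <- 0; st@Pba <- 0; st@D <- 0.6
  expect_equal(wallFlux(st, tis, p, wall = 1), 0)

  ## PD term alone: 0.8 * 0.6 * (1 - 0) = 0.48 cell/s
  st@A <- c(1, 0); st@D <- 0.6
  pd0 <- pinpdParams(Tpin = 0)
  expect_equal(wallFlux(st, tis, pd0, wall = 1), 0.48)

  ## PIN term alone: 6 * 1 * (1 / (1 + 1)) = 3
  st@A <- c(1, 0); st@D <- 0; st@Pab <- 1; st@Pba <- 0
  expect_equal(wallFlux(st, tis, p, wall = 1), 3)

  ## antisymmetry: exchanging the roles of the two cells (state and
  ## membrane sides) negates the flux, on random two-cell states
  p2 <- pinpdParams(cMarginPlacement = "off")
  for (seed in 1:5) {
    st2 <- randomState(tis, p2, seed)
    mirrored <- st2
    mirrored@A <- rev(st2@A)
    mirrored@Aprec <- rev(st2@Aprec)
    mirrored@Pcyto <- rev(st2@Pcyto)
    mirrored@Pab <- st2@Pba
    mirrored@Pba <- st2@Pab
    expect_equal(wallFlux(mirrored, tis, p2, wall = 1),
                 -wallFlux(st2, tis, p2, wall = 1))
  }
})

test_that("rhsAuxin covers production, decay and transport cancellation", {
  t1 <- makeSquareGrid(1, 1, zoneSpec = list())  # isolated non-zone cell
  p <- pinpdParams()
  st <- initState(t1, p)
  expect_equal(rhsAuxin(st, t1, p, cell = 1), 0)

  st@Aprec <- 0.5
  expect_equal(rhsAuxin(st, t1, p, cell = 1), 15)  # 30 * 0.5

  ## two-cell: transport cancels in the sum
  tis <- twoCellTissue()
  st2 <- randomState(tis, p, 42)
  dA <- rhsAuxin(st2, tis, p)
  prodDecay <- p@auxpr * st2@Aprec - p@auxdec * st2@A
  expect_equal(sum(dA), sum(prodDecay), tolerance = 1e-12)
})

test_that("rhsPd matches direct substitution and its fixed point", {
  p <- pinpdParams()
  tis <- twoCellTissue()
  st <- initState(tis, p)
  ## at the background level with no flux the PD area is stationary:
  ## beta/gamma = 0.03/0.05 = 0.6
  expect_equal(rhsPd(st, p, wall = 1, phi = 0), 0)
  st@D <- 0
  expect_equal(rhsPd(st, p, wall = 1, phi = 0), 0.03)
  expect_equal(rhsPd(st, p, wall = 1, phi = 10), 1e-4 * 100 + 0.03)
  ## sign-independence of the flux
  st@D <- 0.2
  expect_equal(rhsPd(st, p, wall = 1, phi = -3),
               rhsPd(st, p, wall = 1, phi = 3))
})

test_that("rhsPinMembrane matches hand-evaluated allocation terms", {
  tis <- twoCellTissue()
  p <- pinpdParams(cMarginPlacement = "off")
  st <- initState(tis, p)

  ## no cytoplasmic pool: only detachment
  st@Pab <- 1; st@Pcyto <- c(0, 0)
  expect_equal(rhsPinMembrane(st, tis, p, side = "ab", wall = 1, phi = 0),
               -4e-3)

  ## UTG alone: kU * P/(1+P) * f(A_j); f(100) = 50
  st@Pab <- 0; st@Pcyto <- c(1, 0); st@A <- c(0, 100)
  expect_equal(rhsPinMembrane(st, tis, p, side = "ab", wall = 1, phi = 0),
               4e-3 * (1 / 2) * 50)

  ## WTF saturation limit: P_i/(1+P_i) ~ 1 gives kWq phi^2 + kWl phi
  st@Pcyto <- c(1e9, 0); st@A <- c(0, 0)
  expect_equal(rhsPinMembrane(st, tis, p, side = "ab", wall = 1, phi = 100),
               1e-5 * 1e4 + 3e-3 * 100, tolerance = 1e-6)
  ## the reverse side sees no outward flux: detachment only
  expect_equal(rhsPinMembrane(st, tis, p, side = "ba", wall = 1, phi = 100),
               0)
})

test_that("rhsPinCyto balances production, decay and membrane allocation", {
  tis <- twoCellTissue()
  p <- pinpdParams(cMarginPlacement = "off")
  st <- initState(tis, p)
  expect_equal(rhsPinCyto(st, tis, p, cell = 1), 0)

  ## direct substitution: A=2, P=1, membrane sides fixed via phi=0
  st@A <- c(2, 0); st@Pcyto <- c(1, 0)
  memb <- rhsPinMembrane(st, tis, p, side = "ab", wall = 1)
  expect_equal(rhsPinCyto(st, tis, p, cell = 1),
               5e-3 * 2 - 1e-2 * 1 - memb)
})

test_that("the precursor schedule follows the production-zone timing", {
  tis <- makeSquareGrid(5, 5, zoneSpec = gridZoneSpec(z2Width = 2))
  p <- pinpdParams()
  z1 <- which(zones(tis) == "Z1")[1]
  z2 <- which(zones(tis) == "Z2")[1]
  other <- which(zones(tis) == "INTERIOR")[1]

  expect_equal(precursorAt(tis, 0, p)[z1], 0.5)
  expect_equal(precursorAt(tis, 1000, p)[z1], 0.6)   # 0.5 + 1e-4 * 1000
  expect_equal(precursorAt(tis, 600, p)[z2], 0)      # before 2 h 45 m
  expect_equal(precursorAt(tis, 9900, p)[z2], 0)
  expect_equal(precursorAt(tis, 10900, p)[z2], 0.1)  # 1e-4 * 1000 past start
  expect_equal(precursorAt(tis, 1e5, p)[other], 0)

  ## exogenous-auxin scenario quadruples the initial Z1 level
  p2 <- resolveScenario("IAA_WT")
  expect_equal(precursorAt(tis, 0, p2)[z1], 2)
})

test_that("advance equals the independent transcription of the equations", {
  p <- pinpdParams()
  for (seed in 1:6) {
    tis <- if (seed %% 2) makeSquareGrid(3, 3) else makeIrregularLeaf(9, seed)
    st <- randomState(tis, p, seed)
    for (step in 1:3) {
      viaPkg <- advance(st, tis, p, dt = 0.05, adaptive = FALSE)
      viaOracle <- oracleStep(st, tis, p, 0.05)
      expect_lt(stateRelErr(viaPkg, viaOracle), 1e-12)
      st <- viaPkg
    }
  }
})

test_that("all-zero state only relaxes PD toward its background level", {
  tis <- makeSquareGrid(3, 3, zoneSpec = list())  # no production anywhere
  p <- pinpdParams()
  st <- initState(tis, p)
  st@D <- rep(0.2, nWalls(tis))
  st2 <- advance(st, tis, p, dt = 1, adaptive = FALSE)
  expect_equal(st2@A, st@A)
  expect_equal(st2@Pcyto, st@Pcyto)
  expect_true(all(st2@D > st@D))            # relaxing up toward 0.6
  expect_true(all(st2@D < pdSteadyState(p)))
})

test_that("two-cell PD-only equilibration matches the closed form", {
  ## with alpha = beta = gamma = 0 and no production/decay, the auxin
  ## difference decays as exp(-2 D D_ij t)
  tis <- twoCellTissue()
  p <- pinpdParams(Tpin = 0, alpha = 0, beta = 0, gamma = 0,
                   auxpr = 0, auxdec = 0, auxdecSink = 0,
                   pinpr = 0, pindec = 0, z1Init = 0, aprecRamp = 0)
  st <- initState(tis, p)
  st@A <- c(1, 0); st@D <- 0.6
  dt <- 0.01
  for (k in seq_len(500)) st <- advance(st, tis, p, dt, adaptive = FALSE)
  rate <- 2 * p@Dperm * 0.6
  expected <- exp(-rate * 5)  # t = 500 * 0.01
  expect_equal(st@A[1] - st@A[2], expected, tolerance = 1e-2)
  ## total auxin conserved without production or decay
  expect_equal(sum(st@A), 1, tolerance = 1e-12)

  ## first-order convergence: halving dt roughly halves the error
  errAt <- function(dt) {
    s <- initState(tis, p); s@A <- c(1, 0); s@D <- 0.6
    for (k in seq_len(round(5 / dt))) s <- advance(s, tis, p, dt,
                                                   adaptive = FALSE)
    abs((s@A[1] - s@A[2]) - expected)
  }
  e1 <- errAt(0.02); e2 <- errAt(0.01)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
})

test_that("transport conserves auxin and PIN totals are conserved per cell", {
  p <- pinpdParams(pinpr = 0, pindec = 0)
  tis <- makeSquareGrid(4, 4)
  st <- randomState(tis, p, 99)
  prep <- veinsim:::prepareModel(tis, p)
  totalPin <- function(s) {
    owned <- as.numeric(prep$Mown %*% c(s@Pab, s@Pba))
    s@Pcyto + owned
  }
  tot0 <- totalPin(st)
  for (k in 1:50) {
    phi <- wallFlux(st, tis, p)
    ## transport terms sum to zero over the tissue at every step
    transport <- as.numeric(prep$Minc %*% phi)
    expect_lt(abs(sum(transport)), 1e-9)
    st <- advance(st, tis, p, dt = 0.1, adaptive = FALSE)
  }
  ## with pinpr = pindec = 0, per-cell total PIN is invariant
  expect_lt(max(abs(totalPin(st) - tot0)), 1e-9)
})

test_that("mirror-symmetric tissues stay mirror-symmetric", {
  tis <- makeSquareGrid(5, 4)  # Z1 columns 2-4 top, sink columns 2-4 base
  p <- pinpdParams()
  st <- initState(tis, p)
  for (k in 1:200) st <- advance(st, tis, p, dt = 1)
  A <- matrix(st@A, 5, 4)
  expect_equal(A, A[5:1, ], tolerance = 1e-10)
})

test_that("runSimulation records snapshots and handles tEnd = 0", {
  tis <- makeSquareGrid(3, 3)
  p <- pinpdParams()
  r0 <- runSimulation(tis, p, tEnd = 0)
  expect_equal(length(snapshots(r0)), 1)
  expect_equal(snapshotTimes(r0), 0)

  r <- runSimulation(tis, p, tEnd = 30, dt = 1, snapshotTimes = c(0, 10, 30))
  expect_equal(snapshotTimes(r), c(0, 10, 30))
  expect_equal(simTime(snapshots(r)[[3]]), 30)
  ## determinism
  r2 <- runSimulation(tis, p, tEnd = 30, dt = 1, snapshotTimes = c(0, 10, 30))
  expect_identical(auxin(snapshots(r)[[3]]), auxin(snapshots(r2)[[3]]))
})

test_that("non-finite states abort with a diagnostic", {
  tis <- twoCellTissue()
  p <- pinpdParams()
  st <- initState(tis, p)
  st@A <- c(1e308, 0)
  st@D <- 1e308
  expect_error(advance(st, tis, p, dt = 1, adaptive = FALSE), "non-finite")
})
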