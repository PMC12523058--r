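test_that("scenario presets patch the reference parameters as published", {
  wt <- resolveScenario("WT")
  expect_equal(wt@Tpin, 6)
  expect_equal(wt@beta, 3e-2)
  expect_equal(wt@gamma, 5e-2)
  expect_equal(wt@z1Init, 0.5)

  expect_equal(resolveScenario("PIN_PAT_I")@Tpin, 0)
  expect_equal(resolveScenario("NPA_MODERATE")@Tpin, 2)
  expect_equal(resolveScenario("NPA_STRONG")@Tpin, 1.5)

  ## beta/gamma targets via beta with gamma fixed
  cals3 <- resolveScenario("CALS3")
  expect_equal(cals3@beta / cals3@gamma, 0.3)
  expect_equal(cals3@gamma, 5e-2)
  gsl8 <- resolveScenario("GSL8")
  expect_equal(gsl8@beta / gsl8@gamma, 1.2)

  combo <- resolveScenario("GSL8_NPA")
  expect_equal(combo@Tpin, 0)
  expect_equal(combo@beta / combo@gamma, 1.2)

  expect_equal(resolveScenario("IAA_WT")@z1Init, 2)
  expect_equal(resolveScenario("iaa_cals3")@beta, 1.5e-2)  # case-insensitive

  expect_error(resolveScenario("SUPERROOT"), "valid scenarios")
  expect_error(resolveScenario("WT", list(frobnicate = 1)),
               "unknown parameter")
  expect_length(listScenarios(), 11)
})

test_that("scenario patching is order-independent for disjoint overrides", {
  a <- resolveScenario("CALS3", list(Tpin = 3, auxdec = 0.4))
  b <- resolveScenario("CALS3", list(auxdec = 0.4, Tpin = 3))
  for (s in slotNames(a)) expect_identical(slot(a, s), slot(b, s))
})

test_that("config files round-trip driver and model keys", {
  cfg <- file.path(tempdir(), "run.cfg")
  writeLines(c("# surrogate run", "scenario = gsl8", "nx = 5", "ny = 4",
               "t_end = 10", "Tpin = 1.25", "grow = off"), cfg)
  parsed <- readConfig(cfg)
  expect_equal(parsed$scenario, "gsl8")
  expect_equal(parsed$Tpin, "1.25")
  expect_error(readConfig(file.path(tempdir(), "missing.cfg")), "not found")
  expect_error({
    bad <- file.path(tempdir(), "bad.cfg")
    writeLines("justoneword", bad)
    readConfig(bad)
  }, "cannot parse")
})

test_that("runScenario writes snapshots, metrics, manifest and SVG", {
  out <- file.path(tempdir(), "scout")
  res <- runScenario("PIN_PAT_I", geometry = "square", nx = 5, ny = 5,
                     tEnd = 120, snapshotTimes = c(0, 60, 120),
                     outDir = out)
  expect_s4_class(res$run, "SimRun")
  expect_true(all(file.exists(file.path(out,
    c("cells.csv", "walls.csv", "metrics.json", "manifest.json",
      "final.svg")))))
  cells <- read.csv(file.path(out, "cells.csv"))
  expect_equal(sort(unique(cells$t)), c(0, 60, 120))
  expect_equal(nrow(cells), 3 * 25)

  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$params$auxpr, 30)
  expect_equal(man$params$Tpin, 0)
  expect_equal(man$scenario, "PIN_PAT_I")
  expect_equal(man$n_cells, 25)

  ## manifest reproducibility: rerunning from the manifest's parameters
  ## gives bit-identical snapshots
  p2 <- do.call(pinpdParams, man$params[setdiff(names(man$params), NULL)])
  tis <- makeSquareGrid(5, 5)
  rerun <- runSimulation(tis, p2, tEnd = 120, dt = man$dt,
                         snapshotTimes = c(0, 60, 120))
  expect_identical(auxin(snapshots(rerun)[[3]]),
                   auxin(snapshots(res$run)[[3]]))
  expect_equal(man$geometry_hash, veinsim:::geometryHash(tis))
})

test_that("the command-line driver runs, lists scenarios and rejects bad input", {
  expect_output(status <- veinsimMain("--list-scenarios"), "WT")
  expect_equal(status, 0L)

  out <- file.path(tempdir(), "cliout")
  st <- suppressMessages(veinsimMain(c(
    "--scenario", "wt", "--geometry", "square", "--nx", "5", "--ny", "5",
    "--t-end", "60", "--snapshots", "0,60", "--out", out,
    "--set", "Tpin=3")))
  expect_equal(st, 0L)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$params$Tpin, 3)

  expect_equal(suppressMessages(veinsimMain(c("--scenario", "nope",
                                              "--t-end", "1"))), 1L)
  expect_equal(suppressMessages(veinsimMain(c("--set", "notakeyvalue"))), 2L)
})

test_that("growth can be driven through the config file", {
  cfg <- file.path(tempdir(), "grow.cfg")
  writeLines(c("scenario = pin_pat_i", "grow = on", "G3 = 50",
               "t_end = 120"), cfg)
  out <- file.path(tempdir(), "growout")
  st <- suppressMessages(veinsimMain(c("--geometry", "square", "--nx", "4",
                                       "--ny", "4", "--config", cfg,
                                       "--out", out)))
  expect_equal(st, 0L)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$growth$G3, 50)
})
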