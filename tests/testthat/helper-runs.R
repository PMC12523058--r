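# Scenario runs shared across acceptance checks, computed once per test
# session. The surrogate leaf is a 21 x 20 square grid (odd width so the
# midvein has a symmetric center column) with the standard zone layout:
# Z1 at the distal center, lateral Z2 pairs at mid-height, basal sink.

.runCache <- new.env(parent = emptyenv())

surrogateGrid <- function() {
  if (is.null(.runCache$grid))
    .runCache$grid <- makeSquareGrid(21, 20,
                                     zoneSpec = gridZoneSpec(z2Width = 2))
  .runCache$grid
}

cachedRun <- function(key, scenario, tEnd, by = 300, tissue = surrogateGrid(),
                      growth = NULL) {
  if (is.null(.runCache[[key]])) {
    params <- resolveScenario(scenario)
    .runCache[[key]] <- runSimulation(
      tissue, params, tEnd = tEnd, dt = 1,
      snapshotTimes = sort(unique(c(seq(0, tEnd, by = by), tEnd))),
      growth = growth)
  }
  .runCache[[key]]
}

stateAt <- function(run, t) run@states[[which(run@times == t)]]
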