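#' Write per-snapshot CSV tables for a run
#'
#' `cells.csv` holds one row per cell and snapshot (t, id, x, y, area,
#' zone, A, A_prec, P_cyto); `walls.csv` one row per wall and snapshot
#' (t, a, b, length, D, P_ab, P_ba, phi).
#'
#' @param run A [SimRun-class] object.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
writeSnapshotCSV <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cellRows <- list(); wallRows <- list()
  for (k in seq_along(run@times)) {
    tis <- run@tissues[[k]]; st <- run@states[[k]]
    cen <- cellCentroids(tis)
    cellRows[[k]] <- data.frame(
      t = st@t, id = seq_len(nCells(tis)), x = cen[, 1], y = cen[, 2],
      area = cellAreas(tis), zone = zones(tis),
      A = st@A, A_prec = st@Aprec, P_cyto = st@Pcyto)
    wallRows[[k]] <- data.frame(
      t = st@t, a = tis@wallA, b = tis@wallB, length = wallLengths(tis),
      D = st@D, P_ab = st@Pab, P_ba = st@Pba, phi = st@phi)
  }
  utils::write.csv(do.call(rbind, cellRows), file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, wallRows), file.path(dir, "walls.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

## Stable content hash of the tissue geometry (nodes + polygons), for
## run manifests.
geometryHash <- function(tissue) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(list(round(tissue@nodes, 9), tissue@cellNodes, tissue@zone),
            con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: full
#' parameter set, scenario/geometry arguments, seed, time controls and a
#' hash of the tissue geometry.
#'
#' @param run A [SimRun-class] object.
#' @param path Output JSON path.
#' @param extra Named list merged into the manifest (seed, CLI
#'   arguments, ...).
#' @return `path`, invisibly.
#' @export
writeManifest <- function(run, path, extra = list()) {
  pars <- lapply(slotNames(run@params), function(s) slot(run@params, s))
  names(pars) <- slotNames(run@params)
  man <- c(list(
    package = "veinsim",
    version = as.character(utils::packageVersion("veinsim")),
    params = pars,
    geometry_kind = run@tissue@geometryKind,
    n_cells = nCells(run@tissue),
    n_walls = nWalls(run@tissue),
    geometry_hash = geometryHash(run@tissues[[1]]),
    snapshot_times = run@times,
    growth = if (is.null(run@growth)) NULL else
      list(G1 = run@growth@G1, G2 = run@growth@G2, G3 = run@growth@G3,
           divisionRatio = run@growth@divisionRatio)
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param metrics A [MetricsReport-class] object.
#' @param path Output JSON path.
#' @param series Optional time-series data.frame (from
#'   [extensionAndSink()]) embedded under `"series"`.
#' @return `path`, invisibly.
#' @export
writeMetricsJSON <- function(metrics, path, series = NULL) {
  out <- list(
    cp_count = metrics@cpCount,
    cp_cells = metrics@cpCells,
    extension_fraction = metrics@extensionFraction,
    reached_sink = metrics@reachedSink,
    time_to_sink = if (is.na(metrics@timeToSink)) NULL else metrics@timeToSink,
    strand_width = metrics@strandWidth,
    pd_anisotropy = if (is.na(metrics@pdAnisotropy)) NULL else
      metrics@pdAnisotropy,
    pin_polarity = metrics@pinPolarity)
  if (!is.null(series)) out$series <- series
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Keys mirror [PinPdParams-class] slot names plus the driver
#' arguments of [runScenario()] (`scenario`, `geometry`, `nx`, `ny`,
#' `n_cells`, `seed`, `dt`, `t_end`, `grow`, `G1`, `G2`, `G3`).
#'
#' @param path Config file path.
#' @return Named list of character values (coerced downstream).
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse config line: '%s'", ln))
    out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Build, run and summarize one scenario
#'
#' High-level driver behind the command line: constructs the tissue
#' (square grid, irregular Voronoi leaf, or imported XML), resolves the
#' scenario parameters, runs the simulation (optionally growing), and
#' computes the metrics report.
#'
#' @param scenario Scenario name (see [listScenarios()]).
#' @param geometry `"square"`, `"leaf"` or `"xml"`.
#' @param nx,ny Grid dimensions for `geometry = "square"`.
#' @param nCellsLeaf Cell count for `geometry = "leaf"`.
#' @param xml Path to a geometry file for `geometry = "xml"`.
#' @param seed Integer seed (leaf generation).
#' @param dt Reporting time step (s).
#' @param tEnd End time (s).
#' @param snapshotTimes Snapshot times (s); default every 900 s plus the
#'   figure timepoints 2 h 30 m, 5 h, 7 h, 15 h that fall before `tEnd`.
#' @param grow Logical: enable growth and division.
#' @param growth A [GrowthParams-class] when `grow` is `TRUE`.
#' @param overrides Named list of parameter overrides.
#' @param outDir Optional output directory for snapshot CSVs, metrics
#'   JSON, manifest JSON and a final-state SVG.
#' @return List with elements `run` ([SimRun-class]), `metrics`
#'   ([MetricsReport-class]) and `series` (extension time series).
#' @export
runScenario <- function(scenario = "WT", geometry = c("square", "leaf", "xml"),
                        nx = 20, ny = 20, nCellsLeaf = 180, xml = NULL,
                        seed = 1, dt = 1, tEnd = 25200,
                        snapshotTimes = NULL, grow = FALSE,
                        growth = growthParams(), overrides = list(),
                        outDir = NULL) {
  geometry <- match.arg(geometry)
  params <- resolveScenario(scenario, overrides)
  tissue <- switch(geometry,
    square = makeSquareGrid(nx, ny),
    leaf = makeIrregularLeaf(nCellsLeaf, seed = seed),
    xml = importVirtualLeafXML(xml, zoneRule = assignLeafZones))
  if (is.null(snapshotTimes)) {
    snapshotTimes <- unique(c(seq(0, tEnd, by = 900),
                              c(9000, 18000, 25200, 54000), tEnd))
    snapshotTimes <- snapshotTimes[snapshotTimes <= tEnd]
  }
  run <- runSimulation(tissue, params, tEnd = tEnd, dt = dt,
                       snapshotTimes = snapshotTimes,
                       growth = if (grow) growth else NULL)
  metrics <- metricsReport(run)
  es <- extensionAndSink(run)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeSnapshotCSV(run, outDir)
    writeMetricsJSON(metrics, file.path(outDir, "metrics.json"),
                     series = es$series)
    writeManifest(run, file.path(outDir, "manifest.json"),
                  extra = list(scenario = toupper(scenario),
                               geometry = geometry, seed = seed,
                               dt = dt, t_end = tEnd))
    tissueToSVG(run@tissues[[length(run@tissues)]],
                file.path(outDir, "final.svg"),
                state = run@states[[length(run@states)]])
  }
  list(run = run, metrics = metrics, series = es$series)
}
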