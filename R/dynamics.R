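## Vectorized evaluation and explicit integration of the four coupled ODE
## families: cell auxin, wall PD area, cytoplasmic PIN, directed membrane
## PIN. The net wall flux phi is frozen at the start of each time step and
## every right-hand side is evaluated against it.

## Per-tissue constants reused across steps: wall incidence (sparse),
## per-wall PIN efficiency, per-cell decay, production-zone masks.
prepareModel <- function(tissue, params) {
  a <- tissue@wallA; b <- tissue@wallB
  n <- nCells(tissue); nw <- length(a)
  Minc <- Matrix::sparseMatrix(i = c(a, b), j = rep(seq_len(nw), 2),
                               x = c(rep(-1, nw), rep(1, nw)),
                               dims = c(n, nw))
  Mown <- Matrix::sparseMatrix(i = c(a, b),
                               j = c(seq_len(nw), nw + seq_len(nw)),
                               x = 1, dims = c(n, 2L * nw))
  zn <- tissue@zone
  producing <- zn %in% c("Z1", "Z2")
  margin <- zn != "INTERIOR"
  damped <- switch(params@cMarginPlacement,
    margin_margin = margin[a] & margin[b],
    producing_interior = (producing[a] & zn[b] == "INTERIOR") |
                         (producing[b] & zn[a] == "INTERIOR"),
    off = rep(FALSE, length(a)))
  Tfac <- params@Tpin * ifelse(damped, params@cMargin, 1)
  auxdec <- ifelse(zn == "SINK", params@auxdecSink, params@auxdec)
  list(a = a, b = b, n = n, nw = nw, Minc = Minc, Mown = Mown,
       Tfac = Tfac, auxdec = auxdec,
       z1 = zn == "Z1", z2 = zn == "Z2")
}

#' Initial simulation state
#'
#' Auxin, cytoplasmic PIN and membrane PIN start at zero; every wall's PD
#' area starts at the flux-free steady state `beta/gamma`, so early flow
#' is isotropic. The precursor field is set by the production-zone
#' schedule at `t = 0` (Z1 at `z1Init`, everything else 0).
#'
#' @param tissue A [Tissue-class] object.
#' @param params A [PinPdParams-class] object.
#' @return A [SimState-class] at `t = 0`.
#' @export
initState <- function(tissue, params) {
  n <- nCells(tissue); nw <- nWalls(tissue)
  bg <- if (params@gamma > 0) pdSteadyState(params) else 0
  st <- new("SimState", t = 0,
            A = numeric(n), Aprec = numeric(n), Pcyto = numeric(n),
            D = rep(bg, nw),
            Pab = numeric(nw), Pba = numeric(nw), phi = numeric(nw))
  st@Aprec <- precursorAt(tissue, 0, params)
  st
}

#' Production-zone precursor schedule
#'
#' Z1 cells carry precursor `z1Init + aprecRamp * t` from `t = 0`; Z2
#' cells carry 0 before `z2Start` (2 h 45 m) and `aprecRamp *
#' (t - z2Start)` after; all other cells (including sinks) carry 0.
#'
#' @param tissue A [Tissue-class] object.
#' @param t Computational time in seconds.
#' @param params A [PinPdParams-class] object.
#' @return Numeric per-cell precursor vector.
#' @export
precursorAt <- function(tissue, t, params) {
  ap <- numeric(nCells(tissue))
  ap[tissue@zone == "Z1"] <- params@z1Init + params@aprecRamp * t
  if (t >= params@z2Start)
    ap[tissue@zone == "Z2"] <- params@aprecRamp * (t - params@z2Start)
  ap
}

#' Net auxin flux across walls
#'
#' The signed flux from wall cell `a` to cell `b`, the sum of the
#' PIN-carried and PD-carried transport:
#' \deqn{\phi_{ab} = T_{eff} (P_{ab} \frac{A_a}{1+A_a} -
#'   P_{ba} \frac{A_b}{1+A_b}) + D\, D_{ab} (A_a - A_b)}
#' `T_eff` is `Tpin`, reduced by the margin efficiency `cMargin` on the
#' walls selected by `cMarginPlacement` (by default walls between two
#' margin cells). Antisymmetric by construction: the flux b to a is the
#' negation.
#'
#' @param state A [SimState-class] object.
#' @param tissue The matching [Tissue-class].
#' @param params A [PinPdParams-class] object.
#' @param wall Optional wall index; default all walls.
#' @return Numeric signed flux (vector over walls, or scalar).
#' @export
wallFlux <- function(state, tissue, params, wall = NULL) {
  prep <- prepareModel(tissue, params)
  phi <- computeFlux(state, prep, params)
  if (is.null(wall)) phi else phi[wall]
}

computeFlux <- function(state, prep, params) {
  fa <- state@A / (1 + state@A)
  prep$Tfac * (state@Pab * fa[prep$a] - state@Pba * fa[prep$b]) +
    params@Dperm * state@D * (state@A[prep$a] - state@A[prep$b])
}

## Evaluate all right-hand sides against a frozen flux.
evalRHS <- function(state, prep, params, phi) {
  A <- state@A
  transport <- as.numeric(prep$Minc %*% phi)
  dA <- params@auxpr * state@Aprec - prep$auxdec * A + transport
  dD <- params@alpha * phi * phi + params@beta - params@gamma * state@D
  ## WTF allocation on a membrane side only recruits PIN for outward flux
  phiAB <- pmax(phi, 0); phiBA <- pmax(-phi, 0)
  fU <- params@fSat * A / (params@fSat + A)
  sat <- state@Pcyto / (1 + state@Pcyto)
  dPab <- params@kU * sat[prep$a] * fU[prep$b] +
    sat[prep$a] * (params@kWq * phiAB^2 + params@kWl * phiAB) -
    params@kOff * state@Pab
  dPba <- params@kU * sat[prep$b] * fU[prep$a] +
    sat[prep$b] * (params@kWq * phiBA^2 + params@kWl * phiBA) -
    params@kOff * state@Pba
  dPcyto <- params@pinpr * A - params@pindec * state@Pcyto -
    as.numeric(prep$Mown %*% c(dPab, dPba))
  list(phi = phi, transport = transport, dA = dA, dD = dD,
       dPab = dPab, dPba = dPba, dPcyto = dPcyto)
}

#' Auxin rate of change per cell
#'
#' Production from the precursor, first-order decay (at `auxdecSink` in
#' SINK cells) and the summed incoming wall fluxes:
#' `auxpr * Aprec_i - auxdec_i * A_i + sum_j phi_ji`. Transport is
#' evaluated against the frozen flux, so summing over all cells cancels
#' the transport terms exactly.
#'
#' @inheritParams wallFlux
#' @param cell Optional cell id; default all cells.
#' @param phi Frozen per-wall flux; defaults to [wallFlux()] of `state`.
#' @return Numeric `dA/dt` (vector over cells, or scalar).
#' @export
rhsAuxin <- function(state, tissue, params, cell = NULL, phi = NULL) {
  prep <- prepareModel(tissue, params)
  if (is.null(phi)) phi <- computeFlux(state, prep, params)
  dA <- evalRHS(state, prep, params, phi)$dA
  if (is.null(cell)) dA else dA[cell]
}

#' Plasmodesmata area rate of change per wall
#'
#' `alpha * phi^2 + beta - gamma * D_ij`: flux-dependent reinforcement
#' (sign-independent through the square), flux-independent background
#' production and first-order decay. Without flux the PD area relaxes to
#' `beta/gamma`.
#'
#' @inheritParams rhsAuxin
#' @param wall Optional wall index; default all walls.
#' @return Numeric `dD_ij/dt` (vector over walls, or scalar).
#' @export
rhsPd <- function(state, params, wall = NULL, phi = state@phi) {
  dD <- params@alpha * phi * phi + params@beta - params@gamma * state@D
  if (is.null(wall)) dD else dD[wall]
}

#' Membrane PIN rate of change for one wall side
#'
#' Up-the-gradient allocation from the cytoplasmic pool (saturating in
#' both the pool and the neighbor's auxin through `f(A) = 100A/(100+A)`),
#' with-the-flux allocation driven by the outward-rectified frozen flux,
#' and first-order detachment:
#' `kU * P_i f(A_j)/(1+P_i) + P_i/(1+P_i) (kWq phi+^2 + kWl phi+)
#'  - kOff * P_ij`.
#'
#' @inheritParams rhsAuxin
#' @param side `"ab"` for the membrane of wall cell `a` facing `b`,
#'   `"ba"` for the reverse side.
#' @param wall Optional wall index; default all walls.
#' @return Numeric `dP_ij/dt` (vector over walls, or scalar).
#' @export
rhsPinMembrane <- function(state, tissue, params, side = c("ab", "ba"),
                           wall = NULL, phi = NULL) {
  side <- match.arg(side)
  prep <- prepareModel(tissue, params)
  if (is.null(phi)) phi <- computeFlux(state, prep, params)
  r <- evalRHS(state, prep, params, phi)
  d <- if (side == "ab") r$dPab else r$dPba
  if (is.null(wall)) d else d[wall]
}

#' Cytoplasmic PIN rate of change per cell
#'
#' Auxin-driven production, first-order decay, minus everything the
#' cell's membrane sides are currently gaining: `pinpr * A_i - pindec *
#' P_i - sum_j dP_ij/dt`. Consequently the total PIN of a cell (pool plus
#' membranes) changes only through production and decay.
#'
#' @inheritParams rhsAuxin
#' @return Numeric `dP_i/dt` (vector over cells, or scalar).
#' @export
rhsPinCyto <- function(state, tissue, params, cell = NULL, phi = NULL) {
  prep <- prepareModel(tissue, params)
  if (is.null(phi)) phi <- computeFlux(state, prep, params)
  d <- evalRHS(state, prep, params, phi)$dPcyto
  if (is.null(cell)) d else d[cell]
}

#' Refresh the precursor field of a state
#'
#' @inheritParams rhsAuxin
#' @param t Time at which to evaluate the schedule; defaults to the
#'   state's own time.
#' @return The state with `Aprec` replaced by [precursorAt()].
#' @export
updatePrecursor <- function(state, tissue, params, t = state@t) {
  state@Aprec <- precursorAt(tissue, t, params)
  state
}

## Stability substep size: Gershgorin-style bound on the auxin transport
## operator (the stiff part; PD and PIN rates are orders slower). Returns
## the largest per-cell outflow rate.
maxOutflowRate <- function(state, prep, params) {
  ## d/dA_i of the PIN efflux term is T P_ij / (1+A_i)^2; the PD term
  ## contributes D D_ij per wall.
  satA <- 1 / (1 + state@A)^2
  pdRate <- params@Dperm * state@D
  rateA <- pdRate + prep$Tfac * state@Pab * satA[prep$a]
  rateB <- pdRate + prep$Tfac * state@Pba * satA[prep$b]
  perCell <- as.numeric(prep$Mown %*% c(rateA, rateB))
  max(prep$auxdec + perCell, params@gamma, params@kOff, params@pindec)
}

#' Advance the simulation by one time step
#'
#' One reporting step of the explicit first-order (Euler) scheme: the
#' wall flux is frozen at the step start, all four right-hand sides are
#' evaluated against it, states are updated and floored at zero, and the
#' precursor schedule is refreshed. With `adaptive = TRUE` (default) the
#' step is internally divided into equal Euler substeps sized from a
#' Gershgorin bound on the auxin-transport operator, so stiff canalized
#' states (high PD area or membrane PIN) remain stable without the caller
#' choosing `dt`; the flux is re-frozen at each substep. Identical inputs
#' always produce bit-identical results.
#'
#' @inheritParams rhsAuxin
#' @param dt Step length in computational seconds (> 0).
#' @param adaptive Subdivide for stability (default `TRUE`). With
#'   `FALSE` exactly one Euler step of length `dt` is taken.
#' @param prep Precomputed model constants (internal use).
#' @return The [SimState-class] at `t + dt`.
#' @export
advance <- function(state, tissue, params, dt = 1, adaptive = TRUE,
                    prep = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(prep)) prep <- prepareModel(tissue, params)
  par <- list(auxpr = params@auxpr, Dperm = params@Dperm,
              alpha = params@alpha, beta = params@beta,
              gamma = params@gamma, kU = params@kU, kWl = params@kWl,
              kWq = params@kWq, kOff = params@kOff, pinpr = params@pinpr,
              pindec = params@pindec, fSat = params@fSat,
              aprecRamp = params@aprecRamp, z1Init = params@z1Init,
              z2Start = params@z2Start)
  res <- .advanceCpp(state@A, state@Aprec, state@Pcyto, state@D,
                     state@Pab, state@Pba, prep$a, prep$b, prep$Tfac,
                     prep$auxdec, prep$z1, prep$z2, par, state@t, dt,
                     adaptive)
  state@A <- res$A; state@Aprec <- res$Aprec; state@Pcyto <- res$Pcyto
  state@D <- res$D; state@Pab <- res$Pab; state@Pba <- res$Pba
  state@phi <- res$phi
  state@t <- state@t + dt
  state
}

#' Run a simulation and collect snapshots
#'
#' Repeatedly [advance()]s the state from `t = 0` (or a supplied initial
#' state) to `tEnd`, recording full state snapshots at the requested
#' times. Optionally the tissue grows and divides: every `growthEvery`
#' seconds the growth step is applied and division-triggering cells are
#' split (see [growStep()], [maybeDivide()]); snapshots then carry their
#' matching tissues. Deterministic for fixed inputs.
#'
#' @param tissue A [Tissue-class] object.
#' @param params A [PinPdParams-class] object.
#' @param tEnd End time in computational seconds.
#' @param dt Reporting step passed to [advance()] (default 1 s).
#' @param snapshotTimes Times (s) at which to keep snapshots; defaults to
#'   every 900 s plus `tEnd`. Times are snapped to multiples of `dt`.
#' @param state Optional initial [SimState-class] (default
#'   [initState()]).
#' @param growth `NULL` (static tissue) or a [GrowthParams-class].
#' @param growthEvery Seconds between growth/division applications
#'   (default 60).
#' @return A [SimRun-class].
#' @export
runSimulation <- function(tissue, params, tEnd, dt = 1,
                          snapshotTimes = NULL, state = NULL,
                          growth = NULL, growthEvery = 60) {
  if (tEnd < 0) stop("tEnd must be >= 0")
  if (is.null(snapshotTimes))
    snapshotTimes <- unique(c(seq(0, tEnd, by = 900), tEnd))
  snapshotTimes <- sort(unique(pmin(round(snapshotTimes / dt) * dt, tEnd)))
  if (is.null(state)) state <- initState(tissue, params)
  prep <- prepareModel(tissue, params)

  states <- list(); tissues <- list(); times <- numeric(0)
  record <- function(st, tis) {
    states[[length(states) + 1L]] <<- st
    tissues[[length(tissues) + 1L]] <<- tis
    times <<- c(times, st@t)
  }
  if (length(snapshotTimes) && snapshotTimes[1] <= 0) {
    record(state, tissue)
    snapshotTimes <- snapshotTimes[-1]
  }
  events <- snapshotTimes
  if (!is.null(growth)) {
    events <- sort(unique(c(events, seq(growthEvery, tEnd, by = growthEvery))))
  }
  for (te in events) {
    nstep <- round((te - state@t) / dt)
    if (nstep > 0) {
      for (k in seq_len(nstep))
        state <- advance(state, tissue, params, dt, prep = prep)
      state@t <- te
    }
    if (!is.null(growth) && te > 0) {
      gs <- growStep(tissue, state, growthEvery, growth, params)
      tissue <- gs$tissue; state <- gs$state
      div <- divideReadyCells(tissue, state, growth, params)
      if (div$changed) {
        tissue <- div$tissue; state <- div$state
        prep <- prepareModel(tissue, params)
      }
    }
    if (te %in% snapshotTimes) record(state, tissue)
  }
  if (state@t < tEnd) {
    nstep <- round((tEnd - state@t) / dt)
    for (k in seq_len(max(nstep, 0)))
      state <- advance(state, tissue, params, dt, prep = prep)
    if (!length(times) || times[length(times)] < state@t) record(state, tissue)
  }
  new("SimRun", tissue = tissue, params = params, times = times,
      states = states, tissues = tissues, growth = growth)
}
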