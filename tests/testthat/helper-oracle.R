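# Independent straight-line transcription of the four ODE families,
# written loop-by-loop against the model definitions, deliberately not
# sharing code with the package internals. Used to cross-check advance().

oracleFlux <- function(state, tissue, params) {
  zn <- zones(tissue)
  phi <- numeric(nWalls(tissue))
  for (w in seq_len(nWalls(tissue))) {
    a <- tissue@wallA[w]; b <- tissue@wallB[w]
    Teff <- params@Tpin
    prodA <- zn[a] %in% c("Z1", "Z2"); prodB <- zn[b] %in% c("Z1", "Z2")
    reduced <- switch(params@cMarginPlacement,
      margin_margin = zn[a] != "INTERIOR" && zn[b] != "INTERIOR",
      producing_interior = (prodA && zn[b] == "INTERIOR") ||
                           (prodB && zn[a] == "INTERIOR"),
      off = FALSE)
    if (reduced) Teff <- Teff * params@cMargin
    pat <- Teff * (state@Pab[w] * state@A[a] / (1 + state@A[a]) -
                     state@Pba[w] * state@A[b] / (1 + state@A[b]))
    pd <- params@Dperm * state@D[w] * (state@A[a] - state@A[b])
    phi[w] <- pat + pd
  }
  phi
}

# One Euler step of length h against the frozen flux; returns the state
# at t + h with all variables floored at zero.
oracleStep <- function(state, tissue, params, h) {
  zn <- zones(tissue)
  n <- nCells(tissue); nw <- nWalls(tissue)
  phi <- oracleFlux(state, tissue, params)
  fU <- function(A) params@fSat * A / (params@fSat + A)

  dPab <- numeric(nw); dPba <- numeric(nw); dD <- numeric(nw)
  for (w in seq_len(nw)) {
    a <- tissue@wallA[w]; b <- tissue@wallB[w]
    dD[w] <- params@alpha * phi[w]^2 + params@beta - params@gamma * state@D[w]
    phiOutA <- max(0, phi[w]); phiOutB <- max(0, -phi[w])
    dPab[w] <- params@kU * state@Pcyto[a] * fU(state@A[b]) / (1 + state@Pcyto[a]) +
      state@Pcyto[a] / (1 + state@Pcyto[a]) *
        (params@kWq * phiOutA^2 + params@kWl * phiOutA) -
      params@kOff * state@Pab[w]
    dPba[w] <- params@kU * state@Pcyto[b] * fU(state@A[a]) / (1 + state@Pcyto[b]) +
      state@Pcyto[b] / (1 + state@Pcyto[b]) *
        (params@kWq * phiOutB^2 + params@kWl * phiOutB) -
      params@kOff * state@Pba[w]
  }
  dA <- numeric(n); dPc <- numeric(n)
  for (i in seq_len(n)) {
    dec <- if (zn[i] == "SINK") params@auxdecSink else params@auxdec
    transport <- 0; memb <- 0
    for (w in seq_len(nw)) {
      if (tissue@wallA[w] == i) { transport <- transport - phi[w]; memb <- memb + dPab[w] }
      if (tissue@wallB[w] == i) { transport <- transport + phi[w]; memb <- memb + dPba[w] }
    }
    dA[i] <- params@auxpr * state@Aprec[i] - dec * state@A[i] + transport
    dPc[i] <- params@pinpr * state@A[i] - params@pindec * state@Pcyto[i] - memb
  }
  out <- state
  out@A <- pmax(state@A + h * dA, 0)
  out@D <- pmax(state@D + h * dD, 0)
  out@Pab <- pmax(state@Pab + h * dPab, 0)
  out@Pba <- pmax(state@Pba + h * dPba, 0)
  out@Pcyto <- pmax(state@Pcyto + h * dPc, 0)
  out@phi <- phi
  out@t <- state@t + h
  out@Aprec <- precursorAt(tissue, out@t, params)
  out
}

# Random small state on a tissue, reproducible under the given seed.
randomState <- function(tissue, params, seed) {
  set.seed(seed)
  n <- nCells(tissue); nw <- nWalls(tissue)
  st <- initState(tissue, params)
  st@A <- runif(n, 0, 5)
  st@Pcyto <- runif(n, 0, 2)
  st@D <- runif(nw, 0.1, 1.5)
  st@Pab <- runif(nw, 0, 1)
  st@Pba <- runif(nw, 0, 1)
  st
}

relErr <- function(x, y) {
  d <- abs(x - y)
  s <- pmax(abs(x), abs(y), 1e-300)
  max(d / s)
}

stateRelErr <- function(s1, s2) {
  max(relErr(s1@A, s2@A), relErr(s1@D, s2@D), relErr(s1@Pab, s2@Pab),
      relErr(s1@Pba, s2@Pba), relErr(s1@Pcyto, s2@Pcyto))
}
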