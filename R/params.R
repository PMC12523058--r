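#' Construct the model parameter set
#'
#' Returns a [PinPdParams-class] populated with the reference values for
#' normal vein patterning; any subset can be overridden by name. Units are
#' computational: seconds for time, amount/cell for concentrations, cell
#' widths for distance. Computational time scales to biological time by
#' roughly a factor of `timeScale` (= 10), used only when reporting.
#'
#' The four ODE families these parameters feed are, for cell `i` with
#' neighbors `j` (wall quantities `D_ij` symmetric, `P_ij` directed):
#'
#' \deqn{dA_i/dt = auxpr \cdot A_{prec,i} - auxdec \cdot A_i
#'   + T \sum_j (P_{ji} \frac{A_j}{1+A_j} - P_{ij} \frac{A_i}{1+A_i})
#'   + D \sum_j D_{ij} (A_j - A_i)}
#' \deqn{dD_{ij}/dt = \alpha \phi^2 + \beta - \gamma D_{ij}}
#' \deqn{dP_i/dt = pinpr \cdot A_i - pindec \cdot P_i - \sum_j dP_{ij}/dt}
#' \deqn{dP_{ij}/dt = k_U \frac{P_i f(A_j)}{1+P_i}
#'   + \frac{P_i}{1+P_i} (k_{Wq} \phi_+^2 + k_{Wl} \phi_+) - k_{off} P_{ij}}
#'
#' with \eqn{f(A) = 100 A / (100 + A)}, \eqn{\phi} the net auxin flux
#' across the wall frozen at the start of each time step, and
#' \eqn{\phi_+} its rectification to the outward direction of the
#' membrane side being allocated.
#'
#' @param ... Named overrides of any [PinPdParams-class] slot.
#' @return A validated [PinPdParams-class] object.
#' @examples
#' p <- pinpdParams()
#' pdSteadyState(p)          # 0.6: background PD area beta/gamma
#' pinpdParams(Tpin = 0)     # plasmodesmata-only transport
#' @export
pinpdParams <- function(...) {
  p <- new("PinPdParams",
    auxpr = 30, auxdec = 0.5, Tpin = 6, Dperm = 0.8,
    alpha = 1e-4, beta = 3e-2, gamma = 5e-2,
    kU = 4e-3, kWl = 3e-3, kWq = 1e-5, kOff = 4e-3,
    pinpr = 5e-3, pindec = 1e-2, cMargin = 0.833,
    cMarginPlacement = "off",
    fSat = 100, auxdecSink = 10, aprecRamp = 1e-4,
    z1Init = 0.5, z2Start = 9900, timeScale = 10)
  overrideParams(p, list(...))
}

#' Apply named overrides to a parameter object
#'
#' @param params A [PinPdParams-class] object.
#' @param overrides Named list of replacement values.
#' @return The patched, re-validated object. Unknown names are an error.
#' @export
overrideParams <- function(params, overrides) {
  if (!length(overrides)) return(params)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("parameter overrides must be named")
  bad <- setdiff(nm, slotNames(params))
  if (length(bad))
    stop(sprintf("unknown parameter(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(slotNames(params), collapse = ", ")))
  for (s in nm) {
    slot(params, s) <- if (s == "cMarginPlacement")
      as.character(overrides[[s]]) else as.numeric(overrides[[s]])
  }
  validObject(params)
  params
}

#' Flux-free steady state of the plasmodesmata area
#'
#' With no auxin flux the PD equation relaxes to `D_ij = beta / gamma`,
#' the background between-cell PD area (0.6 at reference values). All
#' simulations start every wall at this value.
#'
#' @param params A [PinPdParams-class] object.
#' @return Numeric scalar.
#' @export
pdSteadyState <- function(params) params@beta / params@gamma

#' Background wall permeability through plasmodesmata
#'
#' The product of the PD permeability constant and the flux-free PD area,
#' `D * beta/gamma` (0.8 x 0.6 = 0.48 cell/s at reference values): the
#' per-unit-concentration-difference auxin flow across an uncanalized
#' wall.
#'
#' @param params A [PinPdParams-class] object.
#' @return Numeric scalar in cell/s.
#' @export
backgroundWallPermeability <- function(params) params@Dperm * pdSteadyState(params)

#' Order-of-magnitude diffusivity from extension distance and time
#'
#' The simple diffusion estimate `x^2 / (2 t)`, used to relate observed
#' vein extension (e.g. 500 um over 5 days under strong polar-transport
#' inhibition) to an effective diffusivity.
#'
#' @param x Distance (any length unit).
#' @param t Time (any time unit).
#' @return `x^2 / (2 t)` in the corresponding units.
#' @examples
#' diffusivityEstimate(500, 5 * 24 * 3600)  # ~0.29 um^2/s
#' @export
diffusivityEstimate <- function(x, t) x^2 / (2 * t)
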