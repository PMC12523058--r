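## Scenario presets for the biological conditions the model reproduces.
## beta/gamma targets are set through beta with gamma fixed, so the PD
## relaxation timescale 1/gamma is identical across genotypes.
.scenarioTable <- list(
  WT           = list(),
  NPA_MODERATE = list(Tpin = 2),
  NPA_STRONG   = list(Tpin = 1.5),
  PIN_PAT_I    = list(Tpin = 0),
  CALS3        = list(beta = 1.5e-2),
  GSL8         = list(beta = 6e-2),
  CALS3_NPA    = list(beta = 1.5e-2, Tpin = 0),
  GSL8_NPA     = list(beta = 6e-2, Tpin = 0),
  IAA_WT       = list(z1Init = 2),
  IAA_CALS3    = list(z1Init = 2, beta = 1.5e-2),
  IAA_GSL8     = list(z1Init = 2, beta = 6e-2)
)

#' List the available scenario presets
#'
#' @return Character vector of scenario names: wild type (`WT`), graded
#'   PIN-transport inhibition (`NPA_MODERATE` T = 2, `NPA_STRONG` T =
#'   1.5, `PIN_PAT_I` T = 0), PD-aperture mutants (`CALS3` beta/gamma =
#'   0.3, `GSL8` beta/gamma = 1.2), their combinations with full
#'   transport inhibition, and exogenous-auxin variants (`IAA_*`,
#'   initial Z1 precursor 2).
#' @export
listScenarios <- function() names(.scenarioTable)

#' Resolve a scenario into a full parameter set
#'
#' Reference defaults are patched first by the scenario preset, then by
#' user overrides (which therefore win for disjoint keys the order is
#' irrelevant).
#'
#' @param name Scenario name, case-insensitive (see [listScenarios()]).
#' @param overrides Named list of additional [PinPdParams-class] slot
#'   overrides.
#' @return A [PinPdParams-class] object.
#' @examples
#' resolveScenario("CALS3")@beta / resolveScenario("CALS3")@gamma  # 0.3
#' @export
resolveScenario <- function(name, overrides = list()) {
  key <- toupper(name)
  if (!key %in% names(.scenarioTable))
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 name, paste(listScenarios(), collapse = ", ")))
  p <- overrideParams(pinpdParams(), .scenarioTable[[key]])
  overrideParams(p, overrides)
}
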