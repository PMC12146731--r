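## Physical constants used throughout (kJ/mol units for energies).

#' Gas constant in kJ/mol/K
#'
#' The molar gas constant used to convert temperatures to thermal energies
#' RT in kJ/mol.
#' @export
GAS_CONSTANT <- 0.0083144621

#' Elementary charge in coulomb
#' @export
ELEMENTARY_CHARGE <- 1.602176634e-19

#' Thermal energy RT
#'
#' @param temperature temperature in kelvin (> 0).
#' @return RT in kJ/mol.
#' @examples
#' thermalEnergy(310)
#' @export
thermalEnergy <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (kelvin)")
  GAS_CONSTANT * temperature
}

## log(exp(a) + exp(b)) without overflow; a, b may be vectors.
logAddExp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  ## -Inf + -Inf must stay -Inf, not NaN
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

## log(sum(exp(x)))
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
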