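#' Physical constants and unit conventions
#'
#' All interfaces use angstroms for length, kcal/mol for energy, ps for time
#' (fs accepted for integrator steps where noted), atomic mass units for mass
#' and kelvin for temperature. Concentrations are mol/L.
#'
#' @name gcncmc-units
#' @keywords internal
NULL

## CODATA defined value of Avogadro's constant (mol^-1)
AVOGADRO <- 6.02214076e23

## Molar gas constant in kcal mol^-1 K^-1 (CODATA R = 8.31446261815324 J/mol/K)
GAS_CONSTANT_KCAL <- 8.31446261815324 / 4184

## 1 amu (angstrom/ps)^2 in kcal/mol: (1e-3 kg/mol) * (100 m/s)^2 / 4184 J/kcal
MVSQ_TO_KCAL <- 1e-3 * 100^2 / 4184

## angstrom^3 per litre
A3_PER_L <- 1e27

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(298)
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  GAS_CONSTANT_KCAL * temperature
}

#' Inverse thermal energy beta = 1/kT in mol/kcal
#'
#' @param temperature Temperature in kelvin.
#' @return beta in (kcal/mol)^-1.
#' @export
betaKcal <- function(temperature) 1 / kT(temperature)
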