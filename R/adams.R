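## Adams-value machinery: conversions among B, concentration, K_D and
## standard binding free energy.
##
## B_eq(c) = beta mu' + ln(V_GCMC / V(c)) = beta mu' + ln(N_A c V_GCMC);
## the two forms are algebraically identical and both are exposed. B50, the
## Adams value giving 50% occupancy, maps to the dissociation constant via
## the same relation evaluated at c = K_D, and equals the dimensionless
## free energy of transfer from gas phase to the binding site.

#' Average volume per molecule at a concentration
#'
#' V(c) = 1 / (c N_A), converted to cubic angstroms.
#'
#' @param c Concentration in mol/L (> 0).
#' @return Volume per molecule in angstrom^3.
#' @examples
#' volumePerMolecule(0.5)  # ~3321 A^3
#' @export
volumePerMolecule <- function(c) {
  stopifnot(all(c > 0))
  A3_PER_L / (c * AVOGADRO)
}

#' Adams value for a reference concentration
#'
#' @param spec An \linkS4class{AdamsSpec}.
#' @param c Reference-solution concentration (mol/L, > 0).
#' @return Dimensionless Adams value B.
#' @export
bFromConcentration <- function(spec, c) {
  stopifnot(all(c > 0))
  betaKcal(spec@temperature) * spec@muEx +
    log(spec@vGCMC / volumePerMolecule(c))
}

#' Reference concentration implied by an Adams value
#'
#' Exact inverse of \code{\link{bFromConcentration}}:
#' c = exp(B - beta mu') / (N_A V_GCMC).
#'
#' @param spec An \linkS4class{AdamsSpec}.
#' @param b Adams value (any real number).
#' @return Concentration in mol/L.
#' @export
concentrationFromB <- function(spec, b) {
  exp(b - betaKcal(spec@temperature) * spec@muEx) * A3_PER_L /
    (AVOGADRO * spec@vGCMC)
}

#' Adams value at half occupancy for a dissociation constant
#'
#' B50(K_D) = beta mu' + ln(V_GCMC / V(K_D)).
#'
#' @param spec An \linkS4class{AdamsSpec}.
#' @param kd Dissociation constant (mol/L, > 0).
#' @return B50, dimensionless.
#' @export
b50FromKd <- function(spec, kd) {
  stopifnot(all(kd > 0))
  bFromConcentration(spec, kd)
}

#' Dissociation constant from a half-occupancy Adams value
#'
#' Exact inverse of \code{\link{b50FromKd}}.
#'
#' @param spec An \linkS4class{AdamsSpec}.
#' @param b50 Half-occupancy Adams value.
#' @return K_D in mol/L.
#' @export
kdFromB50 <- function(spec, b50) {
  concentrationFromB(spec, b50)
}

#' Standard binding free energy from a dissociation constant
#'
#' dG = kT ln(K_D / c_standard).
#'
#' @param kd Dissociation constant (mol/L, > 0).
#' @param temperature Temperature (K).
#' @param cStandard Standard-state concentration (mol/L), default 1.
#' @return dG in kcal/mol.
#' @examples
#' dgFromKd(0.21, 298)  # ~ -0.92 kcal/mol
#' @export
dgFromKd <- function(kd, temperature, cStandard = 1) {
  stopifnot(all(kd > 0))
  kT(temperature) * log(kd / cStandard)
}

#' Standard binding free energy from B50
#'
#' dG = kT B50 - mu' - kT ln(V_GCMC / V_standard), where V_standard is the
#' per-molecule volume at the standard-state concentration. Algebraically
#' identical to composing \code{\link{kdFromB50}} with \code{\link{dgFromKd}}.
#' The standard error combines kT sigma(B50) and sigma(mu') in quadrature.
#'
#' @param spec An \linkS4class{AdamsSpec}.
#' @param b50 Half-occupancy Adams value.
#' @param b50Se Standard error on b50 (default 0).
#' @return List with dg (kcal/mol) and se.
#' @export
dgFromB50 <- function(spec, b50, b50Se = 0) {
  ktt <- kT(spec@temperature)
  vStd <- volumePerMolecule(spec@cStandard)
  dg <- ktt * b50 - spec@muEx - ktt * log(spec@vGCMC / vStd)
  list(dg = dg, se = sqrt((ktt * b50Se)^2 + spec@muExSe^2))
}

#' Two-state Boltzmann populations
#'
#' For a free-energy difference dF (in units of kT) between two states, the
#' favoured-state probability is p = 1 / (1 + exp(-dF)). Returned as rounded
#' integer percentages.
#'
#' @param dF Free-energy difference in multiples of kT.
#' @return Integer vector c(major, minor) summing to 100.
#' @examples
#' boltzmannPopulation(0.79)  # 69:31
#' @export
boltzmannPopulation <- function(dF) {
  p <- 1 / (1 + exp(-dF))
  major <- round(100 * p)
  c(major, 100 - major)
}
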