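## Alchemical switching: lambda schedules and the soft-core pair potential.

#' Switching time of a nonequilibrium protocol
#'
#' tau = (nPert + 1) * nProp * dt, the wall-clock length of one switch.
#'
#' @param protocol An \linkS4class{NCMCProtocol}.
#' @return Switching time in picoseconds.
#' @examples
#' switchingTime(ncmcProtocol(499, 50, 2))  # 50 ps
#' switchingTime(ncmcProtocol(99, 50, 2))   # 10 ps
#' @export
switchingTime <- function(protocol) {
  (protocol@nPert + 1) * protocol@nProp * protocol@dtFs * 1e-3
}

#' Staged lambda schedule of a switch
#'
#' Returns the nPert + 1 waypoints of (ljLambda, elecLambda). On insertion
#' the Lennard-Jones interactions are switched on fully before the
#' electrostatics (no naked charges at partial steric coupling); a deletion
#' schedule is the exact reverse. Within each stage the spacing is uniform.
#' The LJ stage takes ceiling(stageSplit * nPert) perturbations.
#'
#' @param protocol An \linkS4class{NCMCProtocol}.
#' @param direction Override the protocol direction ("insert" or "delete").
#' @return (nPert + 1) x 2 matrix with columns lj and elec; the first row of
#'   an insertion is (0, 0) and the last (1, 1).
#' @export
lambdaSchedule <- function(protocol, direction = protocol@direction) {
  nPert <- protocol@nPert
  nLJ <- max(1L, min(nPert, as.integer(ceiling(protocol@stageSplit * nPert))))
  nEl <- nPert - nLJ
  k <- 0:nPert
  lj <- pmin(1, k / nLJ)
  elec <- if (nEl > 0) pmax(0, (k - nLJ) / nEl) else as.numeric(k == nPert)
  ## when the LJ stage consumes all perturbations, electrostatics complete
  ## on the final jump together with the last LJ increment
  sched <- cbind(lj = lj, elec = elec)
  if (direction == "delete") {
    sched <- sched[rev(seq_len(nrow(sched))), , drop = FALSE]
  }
  sched
}

#' Soft-core Lennard-Jones pair energy
#'
#' Beutler-style 1-1-6 soft core:
#' U = 4 eps lam (1/(alpha (1 - lam) + (r/sigma)^6)^2
#'              - 1/(alpha (1 - lam) + (r/sigma)^6)).
#' Finite at r = 0 for lam < 1; reduces to plain LJ at lam = 1; identically
#' zero at lam = 0.
#'
#' @param r Site separation (angstrom), vectorised.
#' @param ljLam Coupling lambda in [0, 1].
#' @param eps LJ well depth (kcal/mol).
#' @param sigma LJ diameter (angstrom).
#' @param alpha Soft-core parameter (default 0.5).
#' @return Energy in kcal/mol.
#' @examples
#' softcorePairEnergy(3.4, 1, 0.5, 3.4)       # 0 at r = sigma
#' softcorePairEnergy(0, 0.5, 1, 3.4, 0.5)    # finite at the origin
#' @export
softcorePairEnergy <- function(r, ljLam, eps, sigma, alpha = 0.5) {
  stopifnot(all(r >= 0), ljLam >= 0, ljLam <= 1)
  .softcoreE(r^2, eps, sigma, ljLam, alpha)
}
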