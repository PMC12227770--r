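## Langevin (BAOAB) dynamics and velocity handling.
##
## Units: positions angstrom, velocities angstrom/ps, masses amu, energies
## kcal/mol. Ghost molecules and molecules at lambda 0 are frozen: they are
## neither propagated by forces nor counted in kinetic energy.

KCAL_TO_MVSQ <- 1 / MVSQ_TO_KCAL   # (amu (A/ps)^2) per kcal/mol

## Per-site masses (amu).
.siteMasses <- function(state) {
  m <- state@molecules
  out <- numeric(nrow(state@positions))
  for (i in seq_len(nrow(m))) {
    sp <- state@system@species[[m$species[i]]]
    out[m$start[i]:m$end[i]] <- sp@mass
  }
  out
}

## Logical site mask of mobile (non-frozen) sites under a lambda map.
.mobileSites <- function(state, lambdas) {
  m <- state@molecules
  mob <- logical(nrow(state@positions))
  for (i in seq_len(nrow(m))) {
    if (lambdas[i, 1] > 0 || lambdas[i, 2] > 0) {
      mob[m$start[i]:m$end[i]] <- TRUE
    }
  }
  mob
}

#' Resample velocities from the Maxwell-Boltzmann distribution
#'
#' Draws fresh velocities at the thermostat temperature for the selected
#' molecules; ghost molecules keep zero velocity unless explicitly selected.
#'
#' @param state A \linkS4class{SystemState}.
#' @param molecules Molecule indices to resample (default all real).
#' @return The state with updated velocities.
#' @export
resampleVelocities <- function(state,
                               molecules = which(!state@ghost)) {
  sigma <- sqrt(kT(state@system@temperature) * KCAL_TO_MVSQ /
                  .siteMasses(state))
  m <- state@molecules
  for (i in molecules) {
    rows <- m$start[i]:m$end[i]
    state@velocities[rows, ] <- stats::rnorm(3 * length(rows)) * sigma[rows]
  }
  state
}

#' Instantaneous kinetic temperature
#'
#' Computed over real (non-ghost) sites from the equipartition relation
#' KE = (3/2) n kT.
#'
#' @param state A \linkS4class{SystemState}.
#' @return Temperature in kelvin (NA if no real sites).
#' @export
kineticTemperature <- function(state) {
  mob <- .mobileSites(state, defaultLambdas(state))
  if (!any(mob)) return(NA_real_)
  m <- .siteMasses(state)[mob]
  v2 <- rowSums(state@velocities[mob, , drop = FALSE]^2)
  ke <- 0.5 * sum(m * v2) * MVSQ_TO_KCAL
  2 * ke / (3 * sum(mob) * GAS_CONSTANT_KCAL)
}

#' Propagate a state with BAOAB Langevin dynamics
#'
#' The BAOAB splitting (half kick, half drift, Ornstein-Uhlenbeck, half
#' drift, half kick) samples the configurational thermal distribution with
#' small time-step error. Ghosts and lambda-0 molecules stay frozen; uses
#' R's global random number stream.
#'
#' @param state A \linkS4class{SystemState}.
#' @param nSteps Number of steps (0 returns the state unchanged).
#' @param dtFs Time step in femtoseconds.
#' @param friction Friction coefficient (1/ps); 0 gives velocity-Verlet NVE.
#' @param lambdas Optional per-molecule lambda map.
#' @return The propagated \linkS4class{SystemState}.
#' @export
propagate <- function(state, nSteps, dtFs = 2, friction = 1,
                      lambdas = NULL) {
  nSteps <- as.integer(nSteps)
  if (nSteps <= 0L) return(state)
  if (is.null(lambdas)) lambdas <- defaultLambdas(state)
  mob <- .mobileSites(state, lambdas)
  if (!any(mob)) return(state)
  dt <- dtFs * 1e-3
  mass <- .siteMasses(state)[mob]
  sigma <- sqrt(kT(state@system@temperature) * KCAL_TO_MVSQ / mass)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2) * sigma
  x <- state@positions
  v <- state@velocities
  nm <- sum(mob)
  interacting <- systemHasInteractions(state@system)
  force <- if (interacting) computeForces(state, lambdas) else NULL
  for (s in seq_len(nSteps)) {
    if (interacting) {
      if (any(!is.finite(force[mob, ]))) {
        stop("non-finite force during propagation at step ", s,
             "; potential energy = ", potentialEnergy(state, lambdas))
      }
      a <- force[mob, , drop = FALSE] * (KCAL_TO_MVSQ / mass)
      v[mob, ] <- v[mob, , drop = FALSE] + 0.5 * dt * a
    }
    x[mob, ] <- x[mob, , drop = FALSE] + 0.5 * dt * v[mob, , drop = FALSE]
    v[mob, ] <- c1 * v[mob, , drop = FALSE] +
      c2 * matrix(stats::rnorm(3 * nm), nm, 3)
    x[mob, ] <- x[mob, , drop = FALSE] + 0.5 * dt * v[mob, , drop = FALSE]
    state@positions <- wrapPositions(x, state@system@box)
    x <- state@positions
    if (interacting) {
      force <- computeForces(state, lambdas)
      a <- force[mob, , drop = FALSE] * (KCAL_TO_MVSQ / mass)
      v[mob, ] <- v[mob, , drop = FALSE] + 0.5 * dt * a
    }
  }
  state@velocities <- v
  state
}

#' Widom test-particle estimate of the excess chemical potential
#'
#' Inserts virtual molecules of a species at uniform random positions (and
#' orientations for multi-site species) into equilibrated NVT frames and
#' estimates mu' = -kT ln < exp(-beta dU) >. The standard error comes from
#' block averaging over frames.
#'
#' @param frames List of \linkS4class{SystemState} NVT frames.
#' @param species Species name to insert (must exist in the system).
#' @param nTrials Trial insertions per frame.
#' @param nBlocks Number of frame blocks for the error estimate.
#' @return List with muEx (kcal/mol), se, and the per-block estimates.
#' @export
widomMuEx <- function(frames, species, nTrials = 100, nBlocks = 5) {
  stopifnot(length(frames) >= 1)
  sys <- frames[[1]]@system
  beta <- betaKcal(sys@temperature)
  perFrame <- vapply(frames, function(fr) {
    mean(exp(-beta * widomTrialEnergies(fr, species, nTrials)))
  }, numeric(1))
  overall <- mean(perFrame)
  if (overall <= 0) {
    warning("all Widom trials overlapped; mu_ex is +Inf")
    return(list(muEx = Inf, se = NA_real_, blocks = numeric(0)))
  }
  nBlocks <- max(1L, min(nBlocks, length(perFrame)))
  grp <- cut(seq_along(perFrame), nBlocks, labels = FALSE)
  blockMu <- vapply(split(perFrame, grp), function(b) {
    -kT(sys@temperature) * log(max(mean(b), 1e-300))
  }, numeric(1))
  list(
    muEx = -kT(sys@temperature) * log(overall),
    se = if (nBlocks > 1) stats::sd(blockMu) / sqrt(nBlocks) else NA_real_,
    blocks = blockMu
  )
}

#' Insertion energies of random Widom trials in one frame
#'
#' @param state A \linkS4class{SystemState}.
#' @param species Species name to insert.
#' @param nTrials Number of trial placements.
#' @return Numeric vector of interaction energies (kcal/mol).
#' @export
widomTrialEnergies <- function(state, species, nTrials) {
  sys <- state@system
  sp <- sys@species[[species]]
  if (is.null(sp)) stop("unknown species: ", species)
  centers <- cbind(
    stats::runif(nTrials, 0, sys@box@edge[1]),
    stats::runif(nTrials, 0, sys@box@edge[2]),
    stats::runif(nTrials, 0, sys@box@edge[3])
  )
  vapply(seq_len(nTrials), function(t) {
    st2 <- addMolecule(state, species, centers[t, ],
                       rotation = randomRotation(), ghost = TRUE)
    i <- nrow(st2@molecules)
    moleculeInteractionEnergy(st2, i, ljLam = 1, elecLam = 1)
  }, numeric(1))
}
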