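#' Create a simulation box
#'
#' @param edge Length-3 numeric vector of edge lengths (angstrom), or a single
#'   value for a cube.
#' @param periodic Logical length-3 (or single value) periodicity flags.
#' @return A \linkS4class{SimulationBox}.
#' @examples
#' simulationBox(20)
#' @export
simulationBox <- function(edge, periodic = TRUE) {
  if (length(edge) == 1L) edge <- rep(edge, 3L)
  if (length(periodic) == 1L) periodic <- rep(periodic, 3L)
  new("SimulationBox", edge = as.numeric(edge), periodic = as.logical(periodic))
}

#' Create a molecular species
#'
#' @param name Species identifier.
#' @param siteCoords n x 3 matrix of local site coordinates; default a single
#'   site at the origin.
#' @param epsilon,sigma,charge,mass Per-site parameters, recycled to the
#'   number of sites.
#' @param pairConst,pairRange Optional constant same-species pair energy
#'   (kcal/mol) and its range (angstrom).
#' @return A \linkS4class{SpeciesSpec}.
#' @examples
#' speciesSpec("lj", epsilon = 0.2, sigma = 3.4)
#' @export
speciesSpec <- function(name, siteCoords = matrix(0, 1, 3), epsilon = 0,
                        sigma = 3.4, charge = 0, mass = 40,
                        pairConst = 0, pairRange = Inf) {
  siteCoords <- matrix(as.numeric(siteCoords), ncol = 3)
  n <- nrow(siteCoords)
  new("SpeciesSpec",
    name = name, siteCoords = siteCoords,
    epsilon = rep_len(as.numeric(epsilon), n),
    sigma = rep_len(as.numeric(sigma), n),
    charge = rep_len(as.numeric(charge), n),
    mass = rep_len(as.numeric(mass), n),
    pairConst = as.numeric(pairConst), pairRange = as.numeric(pairRange)
  )
}

#' Create an external binding well
#'
#' @param center Length-3 well centre (angstrom).
#' @param depth Well depth (kcal/mol).
#' @param width Well width (angstrom).
#' @param form "gaussian" (default; smooth forces) or "square".
#' @param species Species name the well acts on; "" applies to all.
#' @return A \linkS4class{BindingWell}.
#' @export
bindingWell <- function(center, depth, width, form = "gaussian", species = "") {
  new("BindingWell",
    center = as.numeric(center), depth = as.numeric(depth),
    width = as.numeric(width), form = form, species = species
  )
}

#' Create a toy system definition
#'
#' @param box A \linkS4class{SimulationBox}.
#' @param species A \linkS4class{SpeciesSpec} or list of them.
#' @param wells List of \linkS4class{BindingWell} objects.
#' @param temperature Thermostat temperature (K).
#' @param cutoff Nonbonded cutoff (angstrom).
#' @param coulomb Evaluate truncated Coulomb terms?
#' @return A \linkS4class{ToySystem}.
#' @examples
#' toySystem(simulationBox(20), speciesSpec("gas"))
#' @export
toySystem <- function(box, species, wells = list(), temperature = 298,
                      cutoff = 12, coulomb = FALSE) {
  if (is(species, "SpeciesSpec")) species <- list(species)
  if (is(wells, "BindingWell")) wells <- list(wells)
  names(species) <- vapply(species, function(s) s@name, character(1))
  new("ToySystem",
    box = box, species = species, wells = wells,
    temperature = as.numeric(temperature), cutoff = as.numeric(cutoff),
    coulomb = isTRUE(coulomb)
  )
}

#' Create a system state
#'
#' Builds a \linkS4class{SystemState} from explicit molecule placements.
#' Velocities default to a Maxwell-Boltzmann draw at the system temperature.
#'
#' @param system A \linkS4class{ToySystem}.
#' @param speciesNames Character vector, one species name per molecule.
#' @param centers nMol x 3 matrix of molecule centres (angstrom).
#' @param ghost Logical per-molecule ghost flags (default all real).
#' @param velocities Optional nSites x 3 velocity matrix.
#' @return A \linkS4class{SystemState}.
#' @export
systemState <- function(system, speciesNames = character(0),
                        centers = matrix(0, 0, 3), ghost = NULL,
                        velocities = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  nMol <- length(speciesNames)
  stopifnot(nrow(centers) == nMol)
  if (is.null(ghost)) ghost <- rep(FALSE, nMol)
  posList <- vector("list", nMol)
  start <- integer(nMol); end <- integer(nMol)
  cursor <- 0L
  for (i in seq_len(nMol)) {
    sp <- system@species[[speciesNames[i]]]
    if (is.null(sp)) stop("unknown species: ", speciesNames[i])
    ns <- nrow(sp@siteCoords)
    posList[[i]] <- sweep(sp@siteCoords, 2, centers[i, ], "+")
    start[i] <- cursor + 1L
    end[i] <- cursor + ns
    cursor <- cursor + ns
  }
  positions <- if (nMol) do.call(rbind, posList) else matrix(0, 0, 3)
  state <- new("SystemState",
    system = system,
    positions = wrapPositions(positions, system@box),
    velocities = matrix(0, nrow(positions), 3),
    molecules = data.frame(
      species = as.character(speciesNames), start = start, end = end,
      stringsAsFactors = FALSE
    ),
    ghost = as.logical(ghost)
  )
  if (is.null(velocities)) {
    state <- resampleVelocities(state)
  } else {
    state@velocities <- velocities
  }
  state
}

#' Create a nonequilibrium switching protocol
#'
#' @param nPert Perturbation steps between end states.
#' @param nProp MD steps between perturbations.
#' @param dtFs Integrator time step (fs).
#' @param direction "insert" or "delete".
#' @param alpha Soft-core parameter.
#' @param stageSplit Fraction of the lambda path in the LJ stage on insertion.
#' @return An \linkS4class{NCMCProtocol}.
#' @examples
#' switchingTime(ncmcProtocol(499, 50, 2))  # 50 ps
#' @export
ncmcProtocol <- function(nPert, nProp, dtFs = 2, direction = "insert",
                         alpha = 0.5, stageSplit = 0.5) {
  new("NCMCProtocol",
    nPert = as.integer(nPert), nProp = as.integer(nProp),
    dtFs = as.numeric(dtFs), direction = direction,
    alpha = as.numeric(alpha), stageSplit = as.numeric(stageSplit)
  )
}

#' Create a GCMC region
#'
#' @param mode "sphere" or "whole_box".
#' @param center Sphere centre (angstrom), ignored for whole_box.
#' @param radius Sphere radius (angstrom).
#' @param anchor Optional site index whose position defines the centre,
#'   re-evaluated at every membership query.
#' @return A \linkS4class{GCMCRegion}.
#' @export
gcmcRegion <- function(mode = c("whole_box", "sphere"), center = c(0, 0, 0),
                       radius = 0, anchor = NULL) {
  mode <- match.arg(mode)
  new("GCMCRegion",
    mode = mode, center = as.numeric(center),
    anchor = if (is.null(anchor)) NULL else as.numeric(anchor),
    radius = as.numeric(radius)
  )
}

#' Create an Adams-value specification
#'
#' @param muEx Excess chemical potential (kcal/mol).
#' @param temperature Temperature (K).
#' @param vGCMC GCMC region volume (angstrom^3).
#' @param muExSe Standard error on muEx.
#' @param cStandard Standard-state concentration (mol/L).
#' @return An \linkS4class{AdamsSpec}.
#' @examples
#' adamsSpec(muEx = -6.09, temperature = 298, vGCMC = 62e3)
#' @export
adamsSpec <- function(muEx, temperature, vGCMC, muExSe = 0, cStandard = 1) {
  new("AdamsSpec",
    muEx = as.numeric(muEx), muExSe = as.numeric(muExSe),
    temperature = as.numeric(temperature), vGCMC = as.numeric(vGCMC),
    cStandard = as.numeric(cStandard)
  )
}

#' Create a chain schedule
#'
#' @param nCycles Total cycles.
#' @param movePattern Species names moved each cycle (one GCNCMC move per
#'   entry).
#' @param mdStepsPerCycle MD steps between move blocks.
#' @param nEquil Equilibration cycles discarded downstream.
#' @param rejectLimit Stop after this many consecutive rejected moves
#'   post-equilibration (Inf to disable).
#' @param mdDtFs MD time step (fs).
#' @param friction Langevin friction (1/ps).
#' @return A \linkS4class{ChainSchedule}.
#' @export
chainSchedule <- function(nCycles, movePattern, mdStepsPerCycle = 10,
                          nEquil = 200, rejectLimit = 200, mdDtFs = 2,
                          friction = 1) {
  new("ChainSchedule",
    nCycles = as.integer(nCycles), movePattern = as.character(movePattern),
    mdStepsPerCycle = as.integer(mdStepsPerCycle),
    nEquil = as.integer(nEquil), rejectLimit = as.numeric(rejectLimit),
    mdDtFs = as.numeric(mdDtFs), friction = as.numeric(friction)
  )
}
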