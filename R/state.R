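## State editing: adding molecules, ghosting, rigid placement.

#' Uniform random rotation matrix
#'
#' Drawn via the quaternion method (uniform on SO(3)).
#'
#' @return 3 x 3 rotation matrix.
#' @export
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Uniform random point inside a GCMC region
#'
#' @param region A \linkS4class{GCMCRegion}.
#' @param state State used for anchored centres and box bounds.
#' @return Length-3 position (angstrom).
#' @export
randomPointInRegion <- function(region, state) {
  box <- state@system@box
  if (region@mode == "whole_box") {
    return(stats::runif(3) * box@edge)
  }
  ctr <- regionCenter(region, state)
  repeat {
    p <- stats::runif(3, -region@radius, region@radius)
    if (sum(p^2) <= region@radius^2) return(ctr + p)
  }
}

#' Add a molecule to a state
#'
#' Appends a molecule of the given species at a centre with an optional
#' rigid rotation. New real molecules get Maxwell-Boltzmann velocities; new
#' ghosts are parked with zero velocity.
#'
#' @param state A \linkS4class{SystemState}.
#' @param species Species name.
#' @param center Length-3 molecule centre (angstrom).
#' @param rotation Optional 3 x 3 rotation applied to the local site frame.
#' @param ghost Add as a ghost (fully decoupled)?
#' @return The extended \linkS4class{SystemState}.
#' @export
addMolecule <- function(state, species, center, rotation = NULL,
                        ghost = FALSE) {
  sp <- state@system@species[[species]]
  if (is.null(sp)) stop("unknown species: ", species)
  local <- sp@siteCoords
  if (!is.null(rotation)) local <- local %*% t(rotation)
  pos <- sweep(local, 2, as.numeric(center), "+")
  ns <- nrow(pos)
  n0 <- nrow(state@positions)
  state@positions <- wrapPositions(rbind(state@positions, pos),
                                   state@system@box)
  state@velocities <- rbind(state@velocities, matrix(0, ns, 3))
  state@molecules <- rbind(state@molecules, data.frame(
    species = species, start = n0 + 1L, end = n0 + ns,
    stringsAsFactors = FALSE
  ))
  state@ghost <- c(state@ghost, ghost)
  i <- nrow(state@molecules)
  if (!ghost) state <- resampleVelocities(state, i)
  state
}

#' Teleport a molecule to a new centre and orientation
#'
#' Rigidly re-places the molecule's sites; velocities are zeroed (the engine
#' resamples them when the molecule is activated).
#'
#' @param state A \linkS4class{SystemState}.
#' @param i Molecule index.
#' @param center New centre (angstrom).
#' @param rotation Optional 3 x 3 rotation for the local frame.
#' @return Updated state.
#' @export
placeMolecule <- function(state, i, center, rotation = NULL) {
  sp <- state@system@species[[state@molecules$species[i]]]
  local <- sp@siteCoords
  if (!is.null(rotation)) local <- local %*% t(rotation)
  rows <- state@molecules$start[i]:state@molecules$end[i]
  state@positions[rows, ] <- sweep(local, 2, as.numeric(center), "+")
  state@positions <- wrapPositions(state@positions, state@system@box)
  state@velocities[rows, ] <- 0
  state
}

#' Set or clear a molecule's ghost flag
#'
#' @param state A \linkS4class{SystemState}.
#' @param i Molecule index.
#' @param ghost New flag.
#' @return Updated state.
#' @export
setGhost <- function(state, i, ghost) {
  state@ghost[i] <- ghost
  if (ghost) {
    rows <- state@molecules$start[i]:state@molecules$end[i]
    state@velocities[rows, ] <- 0
  }
  state
}

#' Ensure a ghost molecule of a species is available
#'
#' Returns the index of a ghost of the species, growing the ghost pool by
#' one parked molecule if none is free.
#'
#' @param state A \linkS4class{SystemState}.
#' @param species Species name.
#' @return List with the (possibly extended) state and the ghost index.
#' @export
ensureGhost <- function(state, species) {
  idx <- which(state@ghost & state@molecules$species == species)
  if (length(idx)) return(list(state = state, index = idx[1]))
  state <- addMolecule(state, species, state@system@box@edge / 2,
                       ghost = TRUE)
  list(state = state, index = nrow(state@molecules))
}

#' Number of real (non-ghost) molecules
#'
#' @param state A \linkS4class{SystemState}.
#' @param species Optional species filter.
#' @return Integer count.
#' @export
nRealMolecules <- function(state, species = NULL) {
  keep <- !state@ghost
  if (!is.null(species)) keep <- keep & state@molecules$species == species
  sum(keep)
}
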