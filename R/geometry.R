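## Periodic geometry helpers shared by the energy, engine and analysis code.

#' Wrap positions into the primary box image
#'
#' @param positions n x 3 matrix (angstrom).
#' @param box A \linkS4class{SimulationBox}.
#' @return Wrapped n x 3 matrix; non-periodic axes are left untouched.
#' @export
wrapPositions <- function(positions, box) {
  if (!nrow(positions)) return(positions)
  for (d in 1:3) {
    if (box@periodic[d]) {
      positions[, d] <- positions[, d] %% box@edge[d]
    }
  }
  positions
}

#' Minimum-image displacement vectors
#'
#' @param delta n x 3 matrix of raw displacement vectors.
#' @param box A \linkS4class{SimulationBox}.
#' @return n x 3 matrix of minimum-image displacements.
#' @export
minimumImage <- function(delta, box) {
  for (d in 1:3) {
    if (box@periodic[d]) {
      L <- box@edge[d]
      delta[, d] <- delta[, d] - L * round(delta[, d] / L)
    }
  }
  delta
}

#' Box volume
#'
#' @param box A \linkS4class{SimulationBox}.
#' @return Volume in angstrom^3.
#' @export
boxVolume <- function(box) prod(box@edge)

#' Molecule centres of geometry
#'
#' The membership point of a molecule is the centre of geometry of its sites.
#'
#' @param state A \linkS4class{SystemState}.
#' @param which Optional molecule indices (default all).
#' @return m x 3 matrix of centres.
#' @export
moleculeCenters <- function(state, which = seq_len(nrow(state@molecules))) {
  m <- state@molecules
  if (!length(which)) return(matrix(0, 0, 3))
  if (all(m$start == m$end)) {
    return(state@positions[m$start[which], , drop = FALSE])
  }
  out <- matrix(0, length(which), 3)
  for (k in seq_along(which)) {
    i <- which[k]
    rows <- m$start[i]:m$end[i]
    out[k, ] <- colMeans(state@positions[rows, , drop = FALSE])
  }
  out
}

#' Current centre of a GCMC region
#'
#' Anchored centres are re-evaluated from the current positions at every call.
#'
#' @param region A \linkS4class{GCMCRegion}.
#' @param state A \linkS4class{SystemState}.
#' @return Length-3 centre (angstrom); box centre in whole_box mode.
#' @export
regionCenter <- function(region, state) {
  if (region@mode == "whole_box") return(state@system@box@edge / 2)
  if (!is.null(region@anchor)) {
    return(as.numeric(state@positions[as.integer(region@anchor[1]), ]))
  }
  region@center
}

#' GCMC region volume
#'
#' @param region A \linkS4class{GCMCRegion}.
#' @param box The \linkS4class{SimulationBox} (needed for whole_box mode).
#' @return Volume in angstrom^3 (4/3 pi r^3 for a sphere).
#' @export
regionVolume <- function(region, box) {
  if (region@mode == "whole_box") return(boxVolume(box))
  4 / 3 * pi * region@radius^3
}

#' Region membership of molecules
#'
#' A molecule is in the region when its centre of geometry lies within the
#' sphere (minimum-image distance to the current centre), or always in
#' whole_box mode. Ghosts are never members.
#'
#' @param state A \linkS4class{SystemState}.
#' @param region A \linkS4class{GCMCRegion}.
#' @return Logical vector, one entry per molecule.
#' @export
inRegion <- function(state, region) {
  nMol <- nrow(state@molecules)
  if (!nMol) return(logical(0))
  member <- !state@ghost
  if (region@mode == "sphere" && any(member)) {
    ctr <- regionCenter(region, state)
    cen <- moleculeCenters(state)
    d <- minimumImage(sweep(cen, 2, ctr, "-"), state@system@box)
    member <- member & (rowSums(d^2) <= region@radius^2)
  }
  member
}

#' Number of real molecules of a species inside a region
#'
#' Always recomputed from geometry; never cached.
#'
#' @param state A \linkS4class{SystemState}.
#' @param region A \linkS4class{GCMCRegion}.
#' @param species Species name, or NULL for all species.
#' @return Integer count.
#' @export
countInRegion <- function(state, region, species = NULL) {
  member <- inRegion(state, region)
  if (!is.null(species)) {
    member <- member & state@molecules$species == species
  }
  sum(member)
}
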