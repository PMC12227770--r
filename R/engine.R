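## The GCNCMC Markov chain: move proposal via nonequilibrium switching,
## grand-canonical acceptance tests, and the MD/move cycle driver.

#' Insertion acceptance probability
#'
#' P = min(1, exp(B) exp(-beta w) / N_T), the sphere-corrected
#' grand-canonical test. N_T counts the molecules of the switched species in
#' the region at the end of the move, including the switched molecule itself.
#'
#' @param w Protocol work (kcal/mol).
#' @param b Adams value.
#' @param nT Region count at move end (>= 1).
#' @param beta Inverse thermal energy (mol/kcal).
#' @return Probability in [0, 1].
#' @examples
#' acceptanceInsert(0, 0, 1, betaKcal(298))       # 1
#' acceptanceInsert(0, -log(2), 1, betaKcal(298)) # 0.5
#' @export
acceptanceInsert <- function(w, b, nT, beta) {
  stopifnot(nT >= 1)
  if (!is.finite(w)) return(0)
  min(1, exp(b - beta * w) / nT)
}

#' Deletion acceptance probability
#'
#' P = min(1, N_0 exp(-B) exp(-beta w)). N_0 counts the molecules of the
#' switched species in the region at the start of the move.
#'
#' @param w Protocol work (kcal/mol).
#' @param b Adams value.
#' @param n0 Region count at move start (>= 1).
#' @param beta Inverse thermal energy (mol/kcal).
#' @return Probability in [0, 1].
#' @export
acceptanceDelete <- function(w, b, n0, beta) {
  stopifnot(n0 >= 1)
  if (!is.finite(w)) return(0)
  min(1, n0 * exp(-b - beta * w))
}

## Move records are built as named lists for speed and assembled into a
## data.frame by recordsToDataFrame (one row per move).
.recordFields <- c(
  "moveType", "species", "work", "N0", "NT", "bUsed",
  "acceptanceProbability", "accepted", "autoRejected", "skipped",
  "rngDraw", "moleculeIndex", "cycle"
)

.newRecord <- function(moveType, species, work, n0, nT, b, skipped = FALSE,
                       autoRejected = FALSE, moleculeIndex = NA_integer_) {
  list(
    moveType = moveType, species = species, work = work,
    N0 = as.integer(n0), NT = as.integer(nT), bUsed = b,
    acceptanceProbability = NA_real_, accepted = FALSE,
    autoRejected = autoRejected, skipped = skipped, rngDraw = NA_real_,
    moleculeIndex = as.integer(moleculeIndex), cycle = NA_integer_
  )
}

#' Assemble move records into a data.frame
#'
#' @param records List of move records (named lists) as produced by
#'   \code{\link{proposeMove}} / \code{\link{finalizeMove}}.
#' @return data.frame with one row per move.
#' @export
recordsToDataFrame <- function(records) {
  if (!length(records)) {
    out <- lapply(.recordFields, function(f) vector(mode = "logical", 0))
    names(out) <- .recordFields
    return(as.data.frame(out))
  }
  out <- lapply(.recordFields, function(f) {
    unlist(lapply(records, function(r) r[[f]]), use.names = FALSE)
  })
  names(out) <- .recordFields
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Propose one GCNCMC move
#'
#' Insertion: a ghost molecule is placed uniformly in the region with a
#' uniform random orientation and coupled along the forward lambda schedule,
#' with nProp thermostatted MD steps between perturbations; the protocol
#' work w is the sum of the fixed-configuration energy changes across the
#' lambda jumps (propagation heat is excluded). Deletion: a uniformly chosen
#' real molecule in the region is decoupled along the reverse schedule. Each
#' move starts and ends with a propagation block. The returned trial state
#' still carries the pre-move ghost flags; \code{\link{finalizeMove}} flips
#' them on acceptance.
#'
#' @param state A \linkS4class{SystemState}.
#' @param region A \linkS4class{GCMCRegion}.
#' @param species Species to move.
#' @param protocol An \linkS4class{NCMCProtocol}; its direction slot is
#'   overridden by \code{direction}.
#' @param direction "insert" or "delete".
#' @param b Adams value used for this move (recorded).
#' @param friction Langevin friction for the in-switch MD (1/ps).
#' @return List with elements trial (state), record (one-row data.frame)
#'   and, for deletions with an empty region, a skipped record.
#' @export
proposeMove <- function(state, region, species, protocol, direction, b,
                        friction = 1) {
  stopifnot(direction %in% c("insert", "delete"))
  member0 <- inRegion(state, region) & state@molecules$species == species
  n0All <- sum(member0)
  if (direction == "delete" && n0All == 0L) {
    rec <- .newRecord("delete", species, NA_real_, 0L, 0L, b,
                      skipped = TRUE)
    rec$acceptanceProbability <- 0
    return(list(trial = state, record = rec))
  }
  if (direction == "insert") {
    g <- ensureGhost(state, species)
    st <- g$state
    tag <- g$index
    st <- placeMolecule(st, tag, randomPointInRegion(region, st),
                        rotation = randomRotation())
    st <- resampleVelocities(st, tag)
    n0 <- countInRegion(st, region, species)
  } else {
    st <- state
    cand <- which(member0)
    tag <- if (length(cand) == 1L) cand else sample(cand, 1L)
    n0 <- n0All
  }
  sched <- lambdaSchedule(protocol, direction)
  lam <- defaultLambdas(st)
  lam[tag, ] <- sched[1, ]
  ## opening propagation block (pure heat, outside the work)
  st <- propagate(st, protocol@nProp, protocol@dtFs, friction, lam)
  w <- 0
  for (k in seq_len(protocol@nPert)) {
    uOld <- moleculeInteractionEnergy(st, tag, sched[k, 1], sched[k, 2], lam)
    uNew <- moleculeInteractionEnergy(st, tag, sched[k + 1, 1],
                                      sched[k + 1, 2], lam)
    w <- w + (uNew - uOld)
    lam[tag, ] <- sched[k + 1, ]
    ## propagation after every perturbation; the final block is the closing
    ## bracket required by tau = (nPert + 1) nProp dt
    st <- propagate(st, protocol@nProp, protocol@dtFs, friction, lam)
  }
  ## region counts at move end; the switched molecule counts itself when its
  ## membership point is inside
  ctrIn <- .moleculeInRegion(st, tag, region)
  nEnd <- countInRegion(st, region, species)
  if (direction == "insert") {
    ## tagged molecule still carries its ghost flag, so add it explicitly
    nT <- nEnd + as.integer(ctrIn)
  } else {
    ## tagged molecule is still flagged real; NT is the count after removal
    nT <- nEnd - as.integer(ctrIn)
  }
  rec <- .newRecord(direction, species, w, n0, nT, b,
                    autoRejected = !ctrIn, moleculeIndex = tag)
  list(trial = st, record = rec)
}

.moleculeInRegion <- function(state, i, region) {
  if (region@mode == "whole_box") return(TRUE)
  ctr <- regionCenter(region, state)
  d <- minimumImage(moleculeCenters(state, i) - rbind(ctr),
                    state@system@box)
  sum(d^2) <= region@radius^2
}

#' Finalize a GCNCMC move
#'
#' Applies the automatic rejection rule (switched molecule outside the
#' sphere at move end breaks detailed balance for the reverse proposal),
#' otherwise draws against the grand-canonical acceptance probability. On
#' acceptance the switched molecule's ghost flag is flipped (and an inserted
#' molecule gets fresh Maxwell-Boltzmann velocities). On rejection a copy of
#' the pre-move state is returned with freshly resampled velocities.
#'
#' @param prev The pre-move \linkS4class{SystemState}.
#' @param trial The trial state from \code{\link{proposeMove}}.
#' @param record The one-row record from \code{\link{proposeMove}}.
#' @param region The \linkS4class{GCMCRegion} (recorded counts were taken
#'   against it).
#' @return List with state (the next chain state) and record (completed).
#' @export
finalizeMove <- function(prev, trial, record, region) {
  beta <- betaKcal(prev@system@temperature)
  if (isTRUE(record$skipped)) {
    return(list(state = prev, record = record))
  }
  tag <- record$moleculeIndex
  p <- 0
  if (!record$autoRejected && is.finite(record$work)) {
    p <- if (record$moveType == "insert") {
      acceptanceInsert(record$work, record$bUsed, record$NT, beta)
    } else {
      acceptanceDelete(record$work, record$bUsed, record$N0, beta)
    }
  } else if (!is.finite(record$work)) {
    record$autoRejected <- TRUE
  }
  record$acceptanceProbability <- p
  u <- stats::runif(1)
  record$rngDraw <- u
  accepted <- !record$autoRejected && u < p
  record$accepted <- accepted
  if (accepted) {
    st <- trial
    if (record$moveType == "insert") {
      st <- setGhost(st, tag, FALSE)
      st <- resampleVelocities(st, tag)
    } else {
      st <- setGhost(st, tag, TRUE)
    }
    return(list(state = st, record = record))
  }
  st <- resampleVelocities(prev)
  list(state = st, record = record)
}

#' Run a GCNCMC/MD chain
#'
#' Alternates MD stretches with GCNCMC moves: each cycle runs
#' \code{mdStepsPerCycle} steps of BAOAB dynamics, then one move (insert or
#' delete with equal probability) per entry of the species move pattern. The
#' per-cycle region count of each pattern species is recorded after the move
#' block (always recomputed from geometry). After the equilibration cycles
#' the chain stops early once \code{rejectLimit} consecutive moves have been
#' rejected.
#'
#' @param state Initial \linkS4class{SystemState}.
#' @param region A \linkS4class{GCMCRegion}.
#' @param schedule A \linkS4class{ChainSchedule}.
#' @param protocols Named list of \linkS4class{NCMCProtocol}, one per moved
#'   species.
#' @param b Named numeric vector of Adams values per moved species.
#' @param saveEvery Save a state snapshot every this many cycles (0 = none).
#' @param checkpointPath Optional path; if propagation fails, the last good
#'   state is serialised there before the error is rethrown.
#' @return List with finalState, records (data.frame of all moves),
#'   occupancy (data.frame cycle x species region counts), frames (list of
#'   saved states) and terminatedEarly flag.
#' @export
runChain <- function(state, region, schedule, protocols, b, saveEvery = 0,
                     checkpointPath = NULL) {
  speciesSet <- unique(schedule@movePattern)
  stopifnot(all(speciesSet %in% names(b)),
            all(speciesSet %in% names(protocols)))
  records <- list()
  occ <- matrix(NA_integer_, schedule@nCycles, length(speciesSet),
                dimnames = list(NULL, speciesSet))
  frames <- list()
  consecReject <- 0L
  terminated <- FALSE
  nDone <- 0L
  for (cyc in seq_len(schedule@nCycles)) {
    if (schedule@mdStepsPerCycle > 0L) {
      state <- tryCatch(
        propagate(state, schedule@mdStepsPerCycle, schedule@mdDtFs,
                  schedule@friction),
        error = function(e) {
          if (!is.null(checkpointPath)) {
            saveRDS(state, checkpointPath)
            stop("propagation failed at cycle ", cyc,
                 "; checkpoint written to ", checkpointPath, ": ",
                 conditionMessage(e))
          }
          stop(e)
        }
      )
    }
    for (spName in schedule@movePattern) {
      direction <- if (stats::runif(1) < 0.5) "insert" else "delete"
      mv <- proposeMove(state, region, spName, protocols[[spName]],
                        direction, b[[spName]], schedule@friction)
      fin <- finalizeMove(state, mv$trial, mv$record, region)
      state <- fin$state
      rec <- fin$record
      rec$cycle <- cyc
      records[[length(records) + 1L]] <- rec
      if (cyc > schedule@nEquil) {
        if (isTRUE(rec$accepted)) {
          consecReject <- 0L
        } else {
          consecReject <- consecReject + 1L
        }
      }
    }
    for (spName in speciesSet) {
      occ[cyc, spName] <- countInRegion(state, region, spName)
    }
    if (saveEvery > 0 && cyc %% saveEvery == 0L) {
      frames[[length(frames) + 1L]] <- state
    }
    nDone <- cyc
    if (cyc > schedule@nEquil && consecReject >= schedule@rejectLimit) {
      terminated <- TRUE
      break
    }
  }
  occ <- occ[seq_len(nDone), , drop = FALSE]
  list(
    finalState = state,
    records = recordsToDataFrame(records),
    occupancy = data.frame(cycle = seq_len(nDone), occ, check.names = FALSE),
    frames = frames,
    terminatedEarly = terminated
  )
}

#' Instantaneous-GCMC protocol
#'
#' The single-perturbation limit of the nonequilibrium switch: one lambda
#' jump whose work is the bare energy change, bracketed by minimal
#' propagation. GCNCMC with this protocol is instantaneous GCMC.
#'
#' @param dtFs Time step for the bracketing propagation (fs).
#' @param nProp Bracketing propagation steps (default 1).
#' @return An \linkS4class{NCMCProtocol} with nPert = 1.
#' @export
instantaneousProtocol <- function(dtFs = 2, nProp = 1) {
  ncmcProtocol(nPert = 1, nProp = nProp, dtFs = dtFs)
}
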