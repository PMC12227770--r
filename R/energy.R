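## Potential energy and forces for toy systems.
##
## Interactions: pairwise soft-core Lennard-Jones (Lorentz-Berthelot mixing,
## plain truncation at the cutoff, no switching function, no long-range
## dispersion correction), optional cutoff-truncated Coulomb scaled linearly
## in the electrostatic lambda, an optional constant same-species pair term
## on molecule centres (square-well pair potential), and external binding
## wells acting on molecule centres. Ghost molecules and molecules at
## lambda = 0 contribute nothing.
##
## Single-site systems (the default) go through vectorised all-pairs code;
## multi-site molecules fall back to an explicit pair loop.

COULOMB_KCAL <- 332.06371    # e^2/angstrom -> kcal/mol
PAIR_ENERGY_CAP <- 1e8       # cap per pair term; overlaps stay finite

## Per-molecule lambda map: nMol x 2 matrix (ljLambda, elecLambda).
## Default: 1 for real molecules, 0 for ghosts.
defaultLambdas <- function(state) {
  nMol <- nrow(state@molecules)
  lam <- matrix(1, nMol, 2, dimnames = list(NULL, c("lj", "elec")))
  lam[state@ghost, ] <- 0
  lam
}

.allSingleSite <- function(state) {
  !nrow(state@molecules) || all(state@molecules$start == state@molecules$end)
}

## TRUE when any pairwise or external term can be non-zero; lets the
## ideal-gas paths skip all energy/force work.
systemHasInteractions <- function(sys) {
  if (length(sys@wells)) return(TRUE)
  for (s in sys@species) {
    if (any(s@epsilon > 0) || s@pairConst != 0) return(TRUE)
    if (sys@coulomb && any(s@charge != 0)) return(TRUE)
  }
  FALSE
}

## Per-molecule single-site parameters (vectors over molecules).
.molParams <- function(state) {
  sp <- state@system@species
  nm <- state@molecules$species
  list(
    eps = vapply(sp, function(s) s@epsilon[1], numeric(1))[nm],
    sig = vapply(sp, function(s) s@sigma[1], numeric(1))[nm],
    q = vapply(sp, function(s) s@charge[1], numeric(1))[nm],
    pc = vapply(sp, function(s) s@pairConst, numeric(1))[nm],
    pr = vapply(sp, function(s) s@pairRange, numeric(1))[nm],
    name = nm
  )
}

## Soft-core LJ energy for squared distances r2; eps, sig, lam may be
## vectors. Beutler 1-1-6 form: plain LJ at lam = 1, finite at r = 0 for
## lam < 1.
.softcoreE <- function(r2, eps, sig, lam, alpha = 0.5) {
  a <- alpha * (1 - lam) + (r2 / sig^2)^3
  a <- pmax(a, 1e-12)
  u <- 4 * eps * lam * (1 / a^2 - 1 / a)
  pmin(u, PAIR_ENERGY_CAP)
}

## d/dr of the soft-core LJ energy (same conventions).
.softcoreDEdr <- function(r2, eps, sig, lam, alpha = 0.5) {
  a <- alpha * (1 - lam) + (r2 / sig^2)^3
  a <- pmax(a, 1e-12)
  r <- sqrt(pmax(r2, 1e-20))
  dadr <- 6 * r^5 / sig^6
  4 * eps * lam * (-2 / a^3 + 1 / a^2) * dadr
}

#' Energy of a binding well at distance r
#'
#' @param r Distance from the well centre (angstrom).
#' @param well A \linkS4class{BindingWell}.
#' @return Energy in kcal/mol (vectorised over r).
#' @export
wellEnergy <- function(r, well) {
  if (well@form == "gaussian") {
    -well@depth * exp(-r^2 / (2 * well@width^2))
  } else {
    ifelse(r <= well@width, -well@depth, 0)
  }
}

## External well energy for molecule centres cogs (m x 3) of species names
## spName, each scaled by its ljLam (vector).
.wellEnergyCogs <- function(sys, cogs, spName, ljLam) {
  if (!length(sys@wells) || !nrow(cogs)) return(0)
  e <- 0
  for (w in sys@wells) {
    sel <- ljLam > 0
    if (nzchar(w@species)) sel <- sel & (spName == w@species)
    if (!any(sel)) next
    d <- minimumImage(sweep(cogs[sel, , drop = FALSE], 2, w@center, "-"),
                      sys@box)
    e <- e + sum(ljLam[sel] * wellEnergy(sqrt(rowSums(d^2)), w))
  }
  e
}

## ---- single-site fast path ------------------------------------------------

## All-pairs energy of single-site molecules idx (absolute molecule indices)
## with per-molecule lambdas lam (nMol x 2).
.energySingle <- function(state, lam) {
  sys <- state@system
  p <- .molParams(state)
  act <- which(lam[, 1] > 0 | lam[, 2] > 0)
  cogs <- state@positions[state@molecules$start[act], , drop = FALSE]
  e <- .wellEnergyCogs(sys, cogs, p$name[act], lam[act, 1])
  n <- length(act)
  if (n < 2) return(e)
  ut <- which(upper.tri(matrix(0, n, n)))
  ii <- row(matrix(0, n, n))[ut]
  jj <- col(matrix(0, n, n))[ut]
  d <- cogs[ii, , drop = FALSE] - cogs[jj, , drop = FALSE]
  d <- minimumImage(d, sys@box)
  r2 <- rowSums(d^2)
  ii <- act[ii]; jj <- act[jj]
  ## constant pair term is structural, not subject to the nonbonded cutoff
  lamLJall <- pmin(lam[ii, 1], lam[jj, 1])
  same <- p$name[ii] == p$name[jj] & p$pc[ii] != 0 & lamLJall > 0
  if (any(same)) {
    within <- same & r2 <= p$pr[ii]^2
    e <- e + sum(lamLJall[within] * p$pc[ii][within])
  }
  keep <- r2 <= sys@cutoff^2
  if (!any(keep)) return(e)
  ii <- ii[keep]; jj <- jj[keep]; r2 <- r2[keep]
  lamLJ <- lamLJall[keep]
  epsij <- sqrt(p$eps[ii] * p$eps[jj])
  sigij <- (p$sig[ii] + p$sig[jj]) / 2
  nz <- epsij > 0 & lamLJ > 0
  if (any(nz)) {
    e <- e + sum(.softcoreE(r2[nz], epsij[nz], sigij[nz], lamLJ[nz]))
  }
  if (sys@coulomb) {
    lamE <- pmin(lam[ii, 2], lam[jj, 2])
    qq <- p$q[ii] * p$q[jj]
    cz <- qq != 0 & lamE > 0
    if (any(cz)) {
      e <- e + sum(pmin(lamE[cz] * COULOMB_KCAL * qq[cz] / sqrt(r2[cz]),
                        PAIR_ENERGY_CAP))
    }
  }
  e
}

## Interaction of single-site molecule i at (ljLam, elecLam) with all others
## at the map lambdas, plus its external terms.
.interactionSingle <- function(state, i, ljLam, elecLam, lam) {
  sys <- state@system
  p <- .molParams(state)
  xi <- state@positions[state@molecules$start[i], ]
  e <- .wellEnergyCogs(sys, matrix(xi, 1, 3), p$name[i], ljLam)
  oth <- which((lam[, 1] > 0 | lam[, 2] > 0) &
                 seq_len(nrow(lam)) != i)
  if (!length(oth)) return(e)
  xo <- state@positions[state@molecules$start[oth], , drop = FALSE]
  d <- minimumImage(sweep(xo, 2, xi, "-"), sys@box)
  r2 <- rowSums(d^2)
  ## constant pair term is structural, not subject to the nonbonded cutoff
  lamLJall <- pmin(ljLam, lam[oth, 1])
  sameAll <- p$name[oth] == p$name[i] & p$pc[oth] != 0 & lamLJall > 0
  if (any(sameAll)) {
    within <- sameAll & r2 <= p$pr[oth]^2
    e <- e + sum(lamLJall[within] * p$pc[oth][within])
  }
  keep <- r2 <= sys@cutoff^2
  if (!any(keep)) return(e)
  oth <- oth[keep]; r2 <- r2[keep]
  lamLJ <- pmin(ljLam, lam[oth, 1])
  epsij <- sqrt(p$eps[i] * p$eps[oth])
  sigij <- (p$sig[i] + p$sig[oth]) / 2
  nz <- epsij > 0 & lamLJ > 0
  if (any(nz)) {
    e <- e + sum(.softcoreE(r2[nz], epsij[nz], sigij[nz], lamLJ[nz]))
  }
  if (sys@coulomb) {
    lamE <- pmin(elecLam, lam[oth, 2])
    qq <- p$q[i] * p$q[oth]
    cz <- qq != 0 & lamE > 0
    if (any(cz)) {
      e <- e + sum(pmin(lamE[cz] * COULOMB_KCAL * qq[cz] / sqrt(r2[cz]),
                        PAIR_ENERGY_CAP))
    }
  }
  e
}

## Forces for single-site systems.
.forcesSingle <- function(state, lam) {
  sys <- state@system
  p <- .molParams(state)
  n <- nrow(state@molecules)
  f <- matrix(0, nrow(state@positions), 3)
  act <- which(lam[, 1] > 0 | lam[, 2] > 0)
  if (!length(act)) return(f)
  rows <- state@molecules$start
  cogs <- state@positions[rows[act], , drop = FALSE]
  ## wells (gaussian only; square wells exert no force)
  for (w in sys@wells) {
    if (w@form != "gaussian") next
    sel <- lam[act, 1] > 0
    if (nzchar(w@species)) sel <- sel & (p$name[act] == w@species)
    if (!any(sel)) next
    asel <- act[sel]
    d <- minimumImage(sweep(cogs[sel, , drop = FALSE], 2, w@center, "-"),
                      sys@box)
    r2 <- rowSums(d^2)
    g <- lam[asel, 1] * w@depth * exp(-r2 / (2 * w@width^2)) / w@width^2
    f[rows[asel], ] <- f[rows[asel], , drop = FALSE] - g * d
  }
  if (length(act) >= 2) {
    m <- length(act)
    ut <- which(upper.tri(matrix(0, m, m)))
    ii <- row(matrix(0, m, m))[ut]
    jj <- col(matrix(0, m, m))[ut]
    d <- cogs[ii, , drop = FALSE] - cogs[jj, , drop = FALSE]
    d <- minimumImage(d, sys@box)
    r2 <- rowSums(d^2)
    keep <- r2 <= sys@cutoff^2 & r2 > 0
    if (any(keep)) {
      ai <- act[ii[keep]]; aj <- act[jj[keep]]
      d <- d[keep, , drop = FALSE]
      r2 <- pmax(r2[keep], 1e-12)
      lamLJ <- pmin(lam[ai, 1], lam[aj, 1])
      epsij <- sqrt(p$eps[ai] * p$eps[aj])
      sigij <- (p$sig[ai] + p$sig[aj]) / 2
      dedr <- numeric(length(r2))
      nz <- epsij > 0 & lamLJ > 0
      if (any(nz)) {
        dedr[nz] <- .softcoreDEdr(r2[nz], epsij[nz], sigij[nz], lamLJ[nz])
      }
      if (sys@coulomb) {
        lamE <- pmin(lam[ai, 2], lam[aj, 2])
        qq <- p$q[ai] * p$q[aj]
        dedr <- dedr - lamE * COULOMB_KCAL * qq / r2
      }
      ## d = x_i - x_j; force on i is -dU/dr * d/r
      fv <- -dedr / sqrt(r2) * d
      for (k in seq_along(ai)) {
        f[rows[ai[k]], ] <- f[rows[ai[k]], ] + fv[k, ]
        f[rows[aj[k]], ] <- f[rows[aj[k]], ] - fv[k, ]
      }
    }
  }
  f
}

## ---- generic multi-site path ----------------------------------------------

.molSites <- function(state, i) {
  sp <- state@system@species[[state@molecules$species[i]]]
  rows <- state@molecules$start[i]:state@molecules$end[i]
  list(
    pos = state@positions[rows, , drop = FALSE],
    eps = sp@epsilon, sig = sp@sigma, q = sp@charge, rows = rows, spec = sp
  )
}

.pairEnergyGeneric <- function(mi, mj, ljLam, elecLam, sys) {
  e <- 0
  for (a in seq_len(nrow(mi$pos))) {
    d <- minimumImage(sweep(mj$pos, 2, mi$pos[a, ], "-"), sys@box)
    r2 <- rowSums(d^2)
    keep <- r2 <= sys@cutoff^2
    if (!any(keep)) next
    r2k <- r2[keep]
    epsij <- sqrt(mi$eps[a] * mj$eps[keep])
    sigij <- (mi$sig[a] + mj$sig[keep]) / 2
    nz <- epsij > 0 & ljLam > 0
    if (any(nz)) {
      e <- e + sum(.softcoreE(r2k[nz], epsij[nz], sigij[nz], ljLam))
    }
    if (sys@coulomb && elecLam > 0) {
      qq <- mi$q[a] * mj$q[keep]
      cz <- qq != 0
      if (any(cz)) {
        r <- sqrt(pmax(r2k[cz], 1e-20))
        e <- e + sum(pmin(elecLam * COULOMB_KCAL * qq[cz] / r,
                          PAIR_ENERGY_CAP))
      }
    }
  }
  e
}

.pairConstEnergy <- function(state, i, j, ljLam) {
  si <- state@molecules$species[i]
  if (si != state@molecules$species[j]) return(0)
  sp <- state@system@species[[si]]
  if (sp@pairConst == 0 || ljLam <= 0) return(0)
  d <- minimumImage(moleculeCenters(state, i) - moleculeCenters(state, j),
                    state@system@box)
  if (sum(d^2) <= sp@pairRange^2) ljLam * sp@pairConst else 0
}

## ---- public surface --------------------------------------------------------

#' Total potential energy of a state
#'
#' Sum of pairwise soft-core LJ (plain truncation, minimum image), optional
#' truncated Coulomb, constant same-species pair terms and external well
#' terms, under a per-molecule lambda map. Ghosts and lambda-0 molecules
#' contribute nothing. Overlapping sites at full coupling give a large but
#' finite energy.
#'
#' @param state A \linkS4class{SystemState}.
#' @param lambdas Optional nMol x 2 matrix (columns ljLambda, elecLambda);
#'   default 1 for real molecules, 0 for ghosts.
#' @return Energy in kcal/mol, always finite.
#' @export
potentialEnergy <- function(state, lambdas = NULL) {
  nMol <- nrow(state@molecules)
  if (!nMol || !systemHasInteractions(state@system)) return(0)
  if (is.null(lambdas)) lambdas <- defaultLambdas(state)
  if (.allSingleSite(state)) return(.energySingle(state, lambdas))
  sys <- state@system
  e <- 0
  for (i in seq_len(nMol)) {
    if (lambdas[i, 1] <= 0 && lambdas[i, 2] <= 0) next
    e <- e + .wellEnergyCogs(sys, moleculeCenters(state, i),
                             state@molecules$species[i], lambdas[i, 1])
    if (i == nMol) next
    mi <- .molSites(state, i)
    for (j in seq(i + 1L, nMol)) {
      lj <- min(lambdas[i, 1], lambdas[j, 1])
      le <- min(lambdas[i, 2], lambdas[j, 2])
      if (lj <= 0 && le <= 0) next
      mj <- .molSites(state, j)
      e <- e + .pairEnergyGeneric(mi, mj, lj, le, sys)
      e <- e + .pairConstEnergy(state, i, j, lj)
    }
  }
  e
}

#' Interaction energy of one molecule with the rest of the system
#'
#' The tagged molecule is evaluated at the given lambdas against every other
#' molecule at its map lambda, plus the tagged molecule's external well and
#' pair-constant terms. The change of this quantity across a lambda
#' perturbation at fixed coordinates is the protocol work increment.
#'
#' @param state A \linkS4class{SystemState}.
#' @param i Molecule index.
#' @param ljLam,elecLam Lambdas applied to molecule i.
#' @param lambdas Optional map for the other molecules (default: real at 1,
#'   ghosts at 0).
#' @return Energy in kcal/mol.
#' @export
moleculeInteractionEnergy <- function(state, i, ljLam = 1, elecLam = ljLam,
                                      lambdas = NULL) {
  if (ljLam <= 0 && elecLam <= 0) return(0)
  if (!systemHasInteractions(state@system)) return(0)
  if (is.null(lambdas)) lambdas <- defaultLambdas(state)
  if (.allSingleSite(state)) {
    return(.interactionSingle(state, i, ljLam, elecLam, lambdas))
  }
  sys <- state@system
  mi <- .molSites(state, i)
  e <- .wellEnergyCogs(sys, moleculeCenters(state, i),
                       state@molecules$species[i], ljLam)
  for (j in seq_len(nrow(state@molecules))) {
    if (j == i) next
    lj <- min(ljLam, lambdas[j, 1])
    le <- min(elecLam, lambdas[j, 2])
    if (lj <= 0 && le <= 0) next
    mj <- .molSites(state, j)
    e <- e + .pairEnergyGeneric(mi, mj, lj, le, sys)
    e <- e + .pairConstEnergy(state, i, j, lj)
  }
  e
}

#' Forces on all sites
#'
#' Analytic gradient of \code{\link{potentialEnergy}} excluding the constant
#' pair term (piecewise constant, zero force) and square wells. Ghosts and
#' lambda-0 molecules feel and exert nothing. Multi-site molecules receive
#' well forces distributed equally over their sites.
#'
#' @param state A \linkS4class{SystemState}.
#' @param lambdas Optional per-molecule lambda map as in
#'   \code{\link{potentialEnergy}}.
#' @return nSites x 3 matrix of forces (kcal/mol/angstrom).
#' @export
computeForces <- function(state, lambdas = NULL) {
  if (!nrow(state@molecules) || !systemHasInteractions(state@system)) {
    return(matrix(0, nrow(state@positions), 3))
  }
  if (is.null(lambdas)) lambdas <- defaultLambdas(state)
  if (.allSingleSite(state)) return(.forcesSingle(state, lambdas))
  sys <- state@system
  nMol <- nrow(state@molecules)
  f <- matrix(0, nrow(state@positions), 3)
  for (i in seq_len(nMol)) {
    if (lambdas[i, 1] <= 0 && lambdas[i, 2] <= 0) next
    if (length(sys@wells) && lambdas[i, 1] > 0) {
      rows <- state@molecules$start[i]:state@molecules$end[i]
      cog <- as.numeric(moleculeCenters(state, i))
      spName <- state@molecules$species[i]
      for (w in sys@wells) {
        if (w@form != "gaussian") next
        if (nzchar(w@species) && w@species != spName) next
        d <- as.numeric(minimumImage(matrix(cog - w@center, 1, 3), sys@box))
        r2 <- sum(d^2)
        g <- lambdas[i, 1] * w@depth * exp(-r2 / (2 * w@width^2)) / w@width^2
        fw <- -g * d / length(rows)
        f[rows, ] <- sweep(f[rows, , drop = FALSE], 2, fw, "+")
      }
    }
    if (i == nMol) next
    mi <- .molSites(state, i)
    for (j in seq(i + 1L, nMol)) {
      lj <- min(lambdas[i, 1], lambdas[j, 1])
      le <- min(lambdas[i, 2], lambdas[j, 2])
      if (lj <= 0 && le <= 0) next
      mj <- .molSites(state, j)
      for (a in seq_along(mi$rows)) {
        d <- minimumImage(sweep(mj$pos, 2, mi$pos[a, ], "-"), sys@box)
        r2 <- rowSums(d^2)
        keep <- which(r2 <= sys@cutoff^2)
        if (!length(keep)) next
        r2k <- pmax(r2[keep], 1e-12)
        dedr <- numeric(length(keep))
        epsij <- sqrt(mi$eps[a] * mj$eps[keep])
        sigij <- (mi$sig[a] + mj$sig[keep]) / 2
        nz <- epsij > 0 & lj > 0
        if (any(nz)) {
          dedr[nz] <- dedr[nz] +
            .softcoreDEdr(r2k[nz], epsij[nz], sigij[nz], lj)
        }
        if (sys@coulomb && le > 0) {
          qq <- mi$q[a] * mj$q[keep]
          dedr <- dedr - le * COULOMB_KCAL * qq / r2k
        }
        ## d points from site a of mol i to sites of mol j
        fj <- dedr / sqrt(r2k) * d[keep, , drop = FALSE]
        f[mj$rows[keep], ] <- f[mj$rows[keep], , drop = FALSE] - fj
        f[mi$rows[a], ] <- f[mi$rows[a], ] + colSums(fj)
      }
    }
  }
  f
}
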