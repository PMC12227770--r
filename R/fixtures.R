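## Deterministic fixture generators with analytic or numerically enumerated
## ground truths. These stand in for force-field systems at desk scale: an
## ideal gas (exact Poisson grand-canonical distribution), a mean-field
## interacting gas (enumerable partition function), single- and double-well
## binding sites (two-state/Boltzmann truths by numerical integration), and
## a synthetic occupancy-table generator for testing the titration fits
## without simulation.

#' Ideal-gas fixture
#'
#' Zero-interaction species in a periodic box with a whole-box GCMC region.
#' The grand-canonical number distribution is exactly Poisson with mean
#' exp(B); the truth block is independent of any seed.
#'
#' @param b Adams value the chain will be run at.
#' @param boxEdge Cubic box edge (angstrom).
#' @param temperature Temperature (K).
#' @param nInitial Initial number of real molecules (default round(exp(b))).
#' @return List with system, state, region, species name and truth
#'   (meanN = varN = exp(b)).
#' @export
makeIdealGas <- function(b = 0, boxEdge = 20, temperature = 298,
                         nInitial = NULL) {
  sp <- speciesSpec("gas", epsilon = 0, sigma = 3, mass = 40)
  sys <- toySystem(simulationBox(boxEdge), sp, temperature = temperature)
  if (is.null(nInitial)) nInitial <- max(0L, round(exp(b)))
  centers <- matrix(stats::runif(3 * nInitial) * boxEdge, ncol = 3)
  state <- systemState(sys, rep("gas", nInitial), centers)
  list(
    system = sys, state = state, region = gcmcRegion("whole_box"),
    species = "gas",
    truth = list(meanN = exp(b), varN = exp(b), b = b)
  )
}

#' Mean-field interacting gas fixture (enumeration oracle)
#'
#' A species whose molecules share a constant pair energy u regardless of
#' separation (square-well pair term with infinite range). The
#' grand-canonical weights are exactly
#' P(N) proportional to exp(B N) exp(-beta u N (N - 1) / 2) / N!,
#' enumerable to machine precision, making this the reference system for
#' validating the sampled number distribution.
#'
#' @param b Adams value.
#' @param pairU Constant pair energy u (kcal/mol).
#' @param boxEdge Cubic box edge (angstrom).
#' @param temperature Temperature (K).
#' @param nMax Truncation for the enumerated distribution.
#' @return List with system, state, region, species and truth (data.frame
#'   N, prob; plus meanN).
#' @export
makeMeanFieldGas <- function(b = 0, pairU = 0.4, boxEdge = 20,
                             temperature = 298, nMax = 30) {
  sp <- speciesSpec("mf", epsilon = 0, sigma = 3, mass = 40,
                    pairConst = pairU, pairRange = Inf)
  sys <- toySystem(simulationBox(boxEdge), sp, temperature = temperature)
  state <- systemState(sys, character(0))
  beta <- betaKcal(temperature)
  n <- 0:nMax
  logw <- b * n - beta * pairU * n * (n - 1) / 2 - lfactorial(n)
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  list(
    system = sys, state = state, region = gcmcRegion("whole_box"),
    species = "mf",
    truth = list(
      dist = data.frame(N = n, prob = prob),
      meanN = sum(n * prob), varN = sum(n^2 * prob) - sum(n * prob)^2,
      b = b, pairU = pairU
    )
  )
}

## Boltzmann weights exp(-beta U(r)) of a single ligand on a regular grid
## over the box; U is the sum of all wells acting on the species.
.wellGridWeights <- function(sys, species, spacing = 0.25) {
  edge <- sys@box@edge
  gx <- seq(spacing / 2, edge[1] - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, edge[2] - spacing / 2, by = spacing)
  gz <- seq(spacing / 2, edge[3] - spacing / 2, by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  u <- numeric(nrow(pts))
  for (w in sys@wells) {
    if (nzchar(w@species) && w@species != species) next
    d <- minimumImage(sweep(pts, 2, w@center, "-"), sys@box)
    u <- u + wellEnergy(sqrt(rowSums(d^2)), w)
  }
  beta <- betaKcal(sys@temperature)
  list(pts = pts, weights = exp(-beta * u), cellVol = spacing^3)
}

#' Single-binding-well fixture with enumerated K_D
#'
#' One gaussian well at the centre of a small box; the GCMC region is the
#' whole box and a hard constant pair repulsion of infinite range enforces
#' single occupancy, so the system is exactly two-state (empty/occupied).
#' The single-molecule configuration integral z = <exp(-beta U)> over the
#' region is computed by deterministic grid quadrature, giving the exact
#' half-occupancy Adams value B50 = -ln z, the dissociation constant and
#' the standard binding free energy for an ideal (mu' = 0) reservoir. The
#' occupancy at any B is the Langmuir form x/(1+x) with x = exp(B) z, i.e.
#' a logistic in B with unit slope.
#'
#' @param depth Well depth (kcal/mol).
#' @param width Well width (angstrom).
#' @param boxEdge Cubic box edge (angstrom).
#' @param temperature Temperature (K).
#' @param gridSpacing Quadrature spacing for the truth integral (angstrom).
#' @return List with system, state (empty region), stateBound (one molecule
#'   parked at the well centre; carries long equilibration transients, see
#'   the package vignette), region, species, spec (AdamsSpec) and truth
#'   (zbar, b50, kd, dg, occupancy function of B).
#' @export
makeSingleWell <- function(depth = 4, width = 1, boxEdge = 10,
                           temperature = 298, gridSpacing = 0.2) {
  sp <- speciesSpec("ligand", epsilon = 0, sigma = 3, mass = 40,
                    pairConst = 1e6, pairRange = Inf)
  well <- bindingWell(rep(boxEdge / 2, 3), depth, width,
                      form = "gaussian", species = "ligand")
  sys <- toySystem(simulationBox(boxEdge), sp, wells = list(well),
                   temperature = temperature)
  state <- systemState(sys, character(0))
  stateBound <- systemState(sys, "ligand", rbind(rep(boxEdge / 2, 3)))
  region <- gcmcRegion("whole_box")
  vol <- boxEdge^3
  gw <- .wellGridWeights(sys, "ligand", gridSpacing)
  zbar <- mean(gw$weights)
  b50 <- -log(zbar)
  spec <- adamsSpec(muEx = 0, temperature = temperature, vGCMC = vol)
  kd <- kdFromB50(spec, b50)
  list(
    system = sys, state = state, stateBound = stateBound, region = region,
    species = "ligand", spec = spec,
    truth = list(
      zbar = zbar, b50 = b50, kd = kd,
      dg = dgFromKd(kd, temperature),
      occupancy = function(b) {
        x <- exp(b) * zbar
        x / (1 + x)
      }
    )
  )
}

#' Double-well binding-site fixture with analytic mode ratio
#'
#' Two gaussian wells of equal width on the x axis, separated left/right of
#' the box centre. The depth of the minor well is solved numerically (grid
#' quadrature of the single-molecule Boltzmann weights over each half-box)
#' so that the half-space populations obey the requested free-energy split
#' dF: p(major)/p(minor) = exp(dF). Single occupancy is enforced as in
#' \code{\link{makeSingleWell}}. The truth block carries the dihedral
#' reference sites and bin edges under which bin 1 corresponds exactly to
#' the major (x > centre) half-space.
#'
#' @param dFkT Free-energy difference between modes in units of kT.
#' @param depth Depth of the major well (kcal/mol).
#' @param width Common well width (angstrom).
#' @param separation Distance between well centres (angstrom).
#' @param boxEdge Cubic box edge (angstrom).
#' @param temperature Temperature (K).
#' @param gridSpacing Quadrature spacing (angstrom).
#' @return List with system, state, region, species, spec, truth (pMajor,
#'   populations, b50, bRun, siteRefs, binEdges, majorBin, wellCenters).
#' @export
makeDoubleWell <- function(dFkT = 0.79, depth = 3, width = 1.2,
                           separation = 5.5, boxEdge = 12, temperature = 298,
                           gridSpacing = 0.2) {
  ctr <- rep(boxEdge / 2, 3)
  cA <- ctr + c(separation / 2, 0, 0)
  cB <- ctr - c(separation / 2, 0, 0)
  sp <- speciesSpec("ligand", epsilon = 0, sigma = 3, mass = 40,
                    pairConst = 1e6, pairRange = Inf)
  boundRadius <- 2.5
  buildSys <- function(depthB) {
    toySystem(
      simulationBox(boxEdge), sp,
      wells = list(
        bindingWell(cA, depth, width, species = "ligand"),
        bindingWell(cB, depthB, width, species = "ligand")
      ),
      temperature = temperature
    )
  }
  ## population of the major mode among bound frames (within boundRadius of
  ## either well centre); the capture spheres do not cross the dividing
  ## plane, so the dihedral (half-space) and distance assignments agree
  popA <- function(depthB) {
    sys <- buildSys(depthB)
    gw <- .wellGridWeights(sys, "ligand", gridSpacing)
    dA2 <- rowSums(sweep(gw$pts, 2, cA, "-")^2)
    dB2 <- rowSums(sweep(gw$pts, 2, cB, "-")^2)
    wA <- sum(gw$weights[dA2 <= boundRadius^2])
    wB <- sum(gw$weights[dB2 <= boundRadius^2])
    wA / (wA + wB)
  }
  target <- 1 / (1 + exp(-dFkT))
  sol <- stats::uniroot(function(dB) popA(dB) - target,
                        lower = 0, upper = depth, tol = 1e-10)
  sys <- buildSys(sol$root)
  gw <- .wellGridWeights(sys, "ligand", gridSpacing)
  zbar <- mean(gw$weights)
  b50 <- -log(zbar)
  state <- systemState(sys, character(0))
  spec <- adamsSpec(muEx = 0, temperature = temperature, vGCMC = boxEdge^3)
  ## anchors give dihedral = atan2(-(x - cx), y - cy): bin (-pi, 0] <=> x > cx
  siteRefs <- list(
    ctr + c(0, 4, 4), ctr + c(0, 0, 4), ctr + c(0, 0, -4),
    list(species = "ligand", site = 1)
  )
  list(
    system = sys, state = state, region = gcmcRegion("whole_box"),
    species = "ligand", spec = spec,
    truth = list(
      pMajor = target, populations = c(major = target, minor = 1 - target),
      ## bRun sits below B50: shorter bound episodes mean more
      ## independent binding events per cycle for population estimates
      dFkT = dFkT, minorDepth = sol$root, b50 = b50, bRun = b50 - 1.5,
      wellCenters = rbind(A = cA, B = cB), center = ctr,
      boundRadius = boundRadius,
      siteRefs = siteRefs, binEdges = c(-pi, 0, pi), majorBin = 1L
    )
  )
}

#' Synthetic occupancy tables with known logistic truth
#'
#' Generates occupancy-vs-B tables directly from the logistic
#' N(B) = 1 / (1 + exp(k (B50 - B))), optionally with binomial counting
#' noise at nCycles observations per row, bypassing simulation entirely.
#'
#' @param b50 True half-occupancy Adams value.
#' @param k True steepness (> 0; rejected otherwise).
#' @param bValues Numeric vector of B values.
#' @param nCycles Cycles per chain (binomial denominator).
#' @param repeats Number of repeats.
#' @param seed Seed for the noise stream.
#' @param noise "binomial" or "none".
#' @return List with table (as from \code{\link{runTitration}}) and truth.
#' @export
makeSyntheticOccupancy <- function(b50, k, bValues, nCycles = 100,
                                   repeats = 4, seed = 1,
                                   noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  if (k <= 0) stop("k must be > 0")
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(childSeed(seed, r))
    p <- 1 / (1 + exp(k * (b50 - bValues)))
    occ <- if (noise == "binomial") {
      stats::rbinom(length(p), nCycles, p) / nCycles
    } else {
      p
    }
    rows[[r]] <- data.frame(
      b = bValues, repeatId = r, occupancy = occ, nCycles = nCycles,
      failed = FALSE
    )
  }
  list(
    table = do.call(rbind, rows),
    truth = list(b50 = b50, k = k)
  )
}
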