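## Shared fixtures and independent oracles for the test suite. The oracles
## deliberately reimplement the physics with plain loops so they share no
## code path with the package internals they check.

## Brute-force total energy: plain LJ + truncated Coulomb + constant
## same-species pair term + external wells, explicit double loop over sites
## with minimum-image convention. All molecules fully coupled.
bruteForceEnergy <- function(state) {
  sys <- state@system
  m <- state@molecules
  real <- which(!state@ghost)
  e <- 0
  ## external wells on centres of geometry
  for (i in real) {
    sp <- m$species[i]
    rows <- m$start[i]:m$end[i]
    cog <- colMeans(state@positions[rows, , drop = FALSE])
    for (w in sys@wells) {
      if (nzchar(w@species) && w@species != sp) next
      d <- cog - w@center
      for (k in 1:3) {
        if (sys@box@periodic[k]) {
          L <- sys@box@edge[k]
          d[k] <- d[k] - L * round(d[k] / L)
        }
      }
      r <- sqrt(sum(d^2))
      e <- e + if (w@form == "gaussian") {
        -w@depth * exp(-r^2 / (2 * w@width^2))
      } else if (r <= w@width) -w@depth else 0
    }
  }
  if (length(real) < 2) return(e)
  for (a in seq_along(real)[-length(real)]) {
    for (b in seq(a + 1, length(real))) {
      i <- real[a]; j <- real[b]
      spi <- sys@species[[m$species[i]]]
      spj <- sys@species[[m$species[j]]]
      ## site-site LJ / Coulomb
      for (si in seq(m$start[i], m$end[i])) {
        for (sj in seq(m$start[j], m$end[j])) {
          d <- state@positions[si, ] - state@positions[sj, ]
          for (k in 1:3) {
            if (sys@box@periodic[k]) {
              L <- sys@box@edge[k]
              d[k] <- d[k] - L * round(d[k] / L)
            }
          }
          r <- sqrt(sum(d^2))
          if (r > sys@cutoff) next
          epsij <- sqrt(spi@epsilon[si - m$start[i] + 1] *
                          spj@epsilon[sj - m$start[j] + 1])
          sigij <- (spi@sigma[si - m$start[i] + 1] +
                      spj@sigma[sj - m$start[j] + 1]) / 2
          if (epsij > 0) {
            sr6 <- (sigij / r)^6
            e <- e + 4 * epsij * (sr6^2 - sr6)
          }
          if (sys@coulomb) {
            qq <- spi@charge[si - m$start[i] + 1] *
              spj@charge[sj - m$start[j] + 1]
            if (qq != 0) e <- e + 332.06371 * qq / r
          }
        }
      }
      ## constant same-species pair term on centres
      if (m$species[i] == m$species[j] && spi@pairConst != 0) {
        ci <- colMeans(state@positions[m$start[i]:m$end[i], , drop = FALSE])
        cj <- colMeans(state@positions[m$start[j]:m$end[j], , drop = FALSE])
        d <- ci - cj
        for (k in 1:3) {
          if (sys@box@periodic[k]) {
            L <- sys@box@edge[k]
            d[k] <- d[k] - L * round(d[k] / L)
          }
        }
        if (sqrt(sum(d^2)) <= spi@pairRange) e <- e + spi@pairConst
      }
    }
  }
  e
}

## Random single-site LJ fluid state.
randomLJState <- function(n, edge = 20, eps = 0.3, sig = 3.4, seed = 1) {
  set.seed(seed)
  sp <- speciesSpec("lj", epsilon = eps, sigma = sig, mass = 40)
  sys <- toySystem(simulationBox(edge), sp, temperature = 298)
  systemState(sys, rep("lj", n), matrix(runif(3 * n) * edge, ncol = 3))
}

## Maxwell speed CDF in the package's units (amu, K, angstrom/ps).
maxwellSpeedCDF <- function(v, mass, temperature) {
  a <- sqrt(kT(temperature) * 418.4 / mass)
  pchisq((v / a)^2, df = 3)
}

## Blocked standard error of the mean of a (possibly autocorrelated) series.
blockedSE <- function(x, nBlocks = 20) {
  nBlocks <- max(2L, min(nBlocks, floor(length(x) / 2)))
  bm <- tapply(x, ceiling(seq_along(x) / (length(x) / nBlocks)), mean)
  stats::sd(bm) / sqrt(length(bm))
}
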