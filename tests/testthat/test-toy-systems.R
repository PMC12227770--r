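test_that("potential energy matches direct expectations on trivial systems", {
  ## two non-interacting particles
  sp <- speciesSpec("gas", epsilon = 0)
  sys <- toySystem(simulationBox(20), sp)
  st <- systemState(sys, c("gas", "gas"), rbind(c(3, 3, 3), c(7, 3, 3)))
  expect_identical(potentialEnergy(st), 0)

  ## full LJ pair at r = sigma crosses zero
  spl <- speciesSpec("lj", epsilon = 0.5, sigma = 3.4)
  sysl <- toySystem(simulationBox(30), spl)
  stl <- systemState(sysl, c("lj", "lj"), rbind(c(5, 5, 5), c(8.4, 5, 5)))
  expect_equal(potentialEnergy(stl), 0, tolerance = 1e-12)

  ## particle at a gaussian well centre sees the full depth
  w <- bindingWell(c(5, 5, 5), depth = 2, width = 1)
  sysw <- toySystem(simulationBox(10), sp, wells = list(w))
  stw <- systemState(sysw, "gas", rbind(c(5, 5, 5)))
  expect_equal(potentialEnergy(stw), -2)

  ## ghosts contribute nothing
  stg <- addMolecule(stl, "lj", c(8.4 + 2, 5, 5), ghost = TRUE)
  expect_equal(potentialEnergy(stg), potentialEnergy(stl))
})

test_that("energy agrees with a brute-force double loop to 1e-10 relative", {
  for (seed in 1:3) {
    st <- randomLJState(40, edge = 18, seed = seed)
    e <- potentialEnergy(st)
    eo <- bruteForceEnergy(st)
    expect_equal(e, eo, tolerance = 1e-10)
  }
  ## with wells, charges and the pair-constant term, multi-species
  set.seed(4)
  spa <- speciesSpec("a", epsilon = 0.2, sigma = 3, charge = 0.2, mass = 20,
                     pairConst = 0.7, pairRange = 6)
  spb <- speciesSpec("b", epsilon = 0.1, sigma = 2.5, charge = -0.2,
                     mass = 30)
  w <- bindingWell(c(9, 9, 9), 1.5, 2, species = "a")
  sys <- toySystem(simulationBox(18), list(spa, spb), wells = list(w),
                   coulomb = TRUE)
  st <- systemState(sys, rep(c("a", "b"), 10),
                    matrix(runif(60) * 18, ncol = 3))
  expect_equal(potentialEnergy(st), bruteForceEnergy(st), tolerance = 1e-10)
})

test_that("energy is invariant under rigid translation and image shifts", {
  st <- randomLJState(20, edge = 16, seed = 7)
  e0 <- potentialEnergy(st)
  shift <- c(3.21, -1.07, 8.5)
  st2 <- st
  st2@positions <- wrapPositions(sweep(st@positions, 2, shift, "+"),
                                 st@system@box)
  expect_equal(potentialEnergy(st2), e0, tolerance = 1e-10)
  ## whole-box image shift of a single molecule
  st3 <- st
  st3@positions[5, ] <- st3@positions[5, ] + st@system@box@edge
  st3@positions <- wrapPositions(st3@positions, st@system@box)
  expect_equal(potentialEnergy(st3), e0, tolerance = 1e-10)
})

test_that("overlapping fully-coupled sites give large finite energy", {
  spl <- speciesSpec("lj", epsilon = 0.5, sigma = 3.4)
  sysl <- toySystem(simulationBox(30), spl)
  stl <- systemState(sysl, c("lj", "lj"), rbind(c(5, 5, 5), c(5, 5, 5)))
  e <- potentialEnergy(stl)
  expect_true(is.finite(e))
  expect_gt(e, 1e6)
})

test_that("propagation with zero steps returns an identical state", {
  st <- randomLJState(10, seed = 2)
  st2 <- propagate(st, 0)
  expect_identical(st2@positions, st@positions)
  expect_identical(st2@velocities, st@velocities)
})

test_that("forces match numerical gradients of the energy", {
  set.seed(10)
  spa <- speciesSpec("a", epsilon = 0.3, sigma = 3, mass = 20)
  w <- bindingWell(c(6, 6, 6), 2, 1.5, species = "a")
  sys <- toySystem(simulationBox(12), spa, wells = list(w))
  st <- systemState(sys, rep("a", 5), matrix(4 + runif(15) * 4, ncol = 3))
  f <- computeForces(st)
  h <- 1e-6
  for (i in c(1, 3, 5)) {
    for (d in 1:3) {
      stp <- st; stp@positions[i, d] <- stp@positions[i, d] + h
      stm <- st; stm@positions[i, d] <- stm@positions[i, d] - h
      num <- -(potentialEnergy(stp) - potentialEnergy(stm)) / (2 * h)
      expect_equal(f[i, d], num, tolerance = 1e-5)
    }
  }
})

test_that("Langevin dynamics thermostats an ideal gas at the target T", {
  set.seed(31)
  sp <- speciesSpec("gas", epsilon = 0, mass = 40)
  sys <- toySystem(simulationBox(30), sp, temperature = 298)
  st <- systemState(sys, rep("gas", 50), matrix(runif(150) * 30, ncol = 3))
  temps <- numeric(80)
  for (i in seq_along(temps)) {
    st <- propagate(st, 25, dtFs = 4, friction = 1)
    temps[i] <- kineticTemperature(st)
  }
  se <- blockedSE(temps, 10)
  expect_lt(abs(mean(temps) - 298), 3 * se + 1e-9)
})

test_that("a particle in a deep gaussian well has the Gibbs position variance", {
  set.seed(32)
  depth <- 8; width <- 1
  w <- bindingWell(c(6, 6, 6), depth, width)
  sp <- speciesSpec("p", epsilon = 0, mass = 40)
  sys <- toySystem(simulationBox(12), sp, wells = list(w), temperature = 298)
  st <- systemState(sys, "p", rbind(c(6, 6, 6)))
  ## quadrature oracle for Var(x) = <r^2>/3 under exp(-beta U(r))
  beta <- betaKcal(298)
  r <- seq(1e-4, 5, length.out = 4000)
  wgt <- exp(beta * depth * exp(-r^2 / (2 * width^2))) * r^2
  varTruth <- sum(wgt * r^2) / sum(wgt) / 3
  xs <- numeric(700)
  for (i in seq_along(xs)) {
    st <- propagate(st, 50, dtFs = 4, friction = 1)
    xs[i] <- st@positions[1, 1]
  }
  xs <- xs[101:length(xs)]
  expect_lt(abs(var(xs) - varTruth), 4 * blockedSE((xs - mean(xs))^2, 10))
})

test_that("the thermostat preserves the Maxwell-Boltzmann speed distribution", {
  set.seed(33)
  sp <- speciesSpec("gas", epsilon = 0, mass = 40)
  sys <- toySystem(simulationBox(40), sp, temperature = 298)
  st <- systemState(sys, rep("gas", 120), matrix(runif(360) * 40, ncol = 3))
  ## frames spaced by ~4 velocity relaxation times so samples are
  ## effectively independent
  speeds <- c()
  for (i in 1:90) {
    st <- propagate(st, 100, dtFs = 4, friction = 10)
    speeds <- c(speeds, sqrt(rowSums(st@velocities^2)))
  }
  expect_gte(length(speeds), 1e4)
  ks <- suppressWarnings(
    ks.test(speeds, function(v) maxwellSpeedCDF(v, 40, 298))
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("Widom insertion gives mu_ex = 0 for an ideal gas and > 0 for a repulsive fluid", {
  set.seed(34)
  sp <- speciesSpec("gas", epsilon = 0, mass = 40)
  sys <- toySystem(simulationBox(20), sp, temperature = 298)
  st <- systemState(sys, rep("gas", 10), matrix(runif(30) * 20, ncol = 3))
  frames <- replicate(10, st, simplify = FALSE)
  est <- widomMuEx(frames, "gas", nTrials = 50)
  expect_equal(est$muEx, 0)

  ## purely repulsive dense system: all insertion energies >= 0
  spr <- speciesSpec("rep", epsilon = 0, sigma = 3, mass = 40,
                     pairConst = 2, pairRange = 50)
  sysr <- toySystem(simulationBox(12), spr, temperature = 298)
  str <- systemState(sysr, rep("rep", 8), matrix(runif(24) * 12, ncol = 3))
  estr <- widomMuEx(list(str, str, str), "rep", nTrials = 50)
  expect_gt(estr$muEx, 0)
})

test_that("Widom mu_ex of a dilute LJ fluid matches the second-virial estimate", {
  set.seed(35)
  eps <- 0.3; sig <- 3.4; Tk <- 298; edge <- 30; n <- 6
  sp <- speciesSpec("lj", epsilon = eps, sigma = sig, mass = 40)
  sys <- toySystem(simulationBox(edge), sp, temperature = Tk, cutoff = 12)
  st <- systemState(sys, rep("lj", n), matrix(runif(3 * n) * edge, ncol = 3))
  st <- propagate(st, 400, 4, 1)
  frames <- list()
  for (i in 1:40) {
    st <- propagate(st, 20, 4, 1)
    frames[[i]] <- st
  }
  est <- widomMuEx(frames, "lj", nTrials = 300)
  ## oracle: mu_ex ~ 2 B2 rho kT at low density, B2 by quadrature of the
  ## truncated potential actually simulated
  beta <- betaKcal(Tk)
  r <- seq(1e-3, 12, length.out = 6000)
  u <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  b2 <- -2 * pi * sum((exp(-beta * u) - 1) * r^2) * diff(r)[1]
  rho <- n / edge^3
  muTruth <- 2 * b2 * rho * kT(Tk)
  expect_lt(abs(est$muEx - muTruth), max(4 * est$se, 0.02))
})
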