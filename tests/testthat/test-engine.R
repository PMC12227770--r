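beta298 <- betaKcal(298)

test_that("acceptance probabilities follow the grand-canonical formulas", {
  expect_equal(acceptanceInsert(0, 0, 1, beta298), 1)
  expect_equal(acceptanceInsert(0, -log(2), 1, beta298), 0.5)
  expect_equal(acceptanceInsert(1e6, 0, 1, beta298), 0)
  expect_equal(acceptanceInsert(0, 0, 4, beta298), 0.25)
  expect_equal(acceptanceDelete(0, 0, 1, beta298), 1)
  expect_equal(acceptanceDelete(0, log(2), 1, beta298), 0.5)
  expect_equal(acceptanceDelete(0, 0, 3, beta298), 1)
  ## Boltzmann factor of the work enters both directions
  w <- 0.7
  expect_equal(acceptanceInsert(w, 0, 1, beta298), exp(-beta298 * w))
  expect_equal(acceptanceDelete(w, 0, 1, beta298), exp(-beta298 * w))
  expect_error(acceptanceInsert(0, 0, 0, beta298))
  expect_error(acceptanceDelete(0, 0, 0, beta298))
})

test_that("insertion proposals land inside the region with zero ideal-gas work", {
  set.seed(71)
  fx <- makeIdealGas(0, boxEdge = 20)
  sphere <- gcmcRegion("sphere", center = c(10, 10, 10), radius = 4)
  for (i in 1:10) {
    mv <- proposeMove(fx$state, sphere, "gas", instantaneousProtocol(),
                      "insert", b = 0)
    expect_identical(mv$record$work, 0)
    cog <- as.numeric(moleculeCenters(mv$trial, mv$record$moleculeIndex))
    expect_lte(sum((cog - c(10, 10, 10))^2), 16 + 1e-9)
  }
})

test_that("deletion with an empty region is recorded as a skipped rejection", {
  set.seed(72)
  fx <- makeIdealGas(0, nInitial = 0)
  mv <- proposeMove(fx$state, fx$region, "gas", instantaneousProtocol(),
                    "delete", b = 0)
  expect_true(mv$record$skipped)
  fin <- finalizeMove(fx$state, mv$trial, mv$record, fx$region)
  expect_false(fin$record$accepted)
  expect_equal(nRealMolecules(fin$state), 0)
})

test_that("auto-rejection applies when the switched molecule leaves the sphere", {
  set.seed(73)
  fx <- makeIdealGas(0, boxEdge = 20, nInitial = 0)
  sphere <- gcmcRegion("sphere", center = c(10, 10, 10), radius = 3)
  mv <- proposeMove(fx$state, sphere, "gas", instantaneousProtocol(),
                    "insert", b = 50)
  ## drag the switched molecule outside the sphere before finalizing
  tag <- mv$record$moleculeIndex
  trial <- placeMolecule(mv$trial, tag, c(1, 1, 1))
  rec <- mv$record
  rec$autoRejected <- TRUE  # as proposeMove would have recorded it
  fin <- finalizeMove(fx$state, trial, rec, sphere)
  expect_false(fin$record$accepted)
  expect_equal(fin$record$acceptanceProbability, 0)
  expect_equal(nRealMolecules(fin$state), 0)
})

test_that("rejected moves restore the previous configuration exactly", {
  set.seed(74)
  fx <- makeIdealGas(0, nInitial = 3)
  ## B = -Inf rejects every insertion
  mv <- proposeMove(fx$state, fx$region, "gas", instantaneousProtocol(),
                    "insert", b = -Inf)
  fin <- finalizeMove(fx$state, mv$trial, mv$record, fx$region)
  expect_false(fin$record$accepted)
  expect_equal(nRealMolecules(fin$state), 3)
  expect_identical(fin$state@positions[1:3, ], fx$state@positions[1:3, ])
  ## velocities are freshly resampled, not copied
  expect_false(identical(fin$state@velocities, fx$state@velocities))
})

test_that("acceptance probability of probability-1 moves is always taken", {
  set.seed(75)
  fx <- makeIdealGas(0, nInitial = 0)
  mv <- proposeMove(fx$state, fx$region, "gas", instantaneousProtocol(),
                    "insert", b = 10)
  fin <- finalizeMove(fx$state, mv$trial, mv$record, fx$region)
  expect_equal(fin$record$acceptanceProbability, 1)
  expect_true(fin$record$accepted)
  expect_equal(nRealMolecules(fin$state), 1)
})

test_that("recorded fields reproduce the engine's accept/reject decisions", {
  set.seed(76)
  fx <- makeMeanFieldGas(b = 0.3, pairU = 0.5)
  sched <- chainSchedule(400, "mf", mdStepsPerCycle = 1, nEquil = 50,
                         rejectLimit = Inf)
  res <- runChain(fx$state, fx$region, sched,
                  list(mf = instantaneousProtocol()), c(mf = 0.3))
  rec <- res$records[!res$records$skipped, ]
  beta <- betaKcal(298)
  pRecomputed <- vapply(seq_len(nrow(rec)), function(r) {
    if (rec$moveType[r] == "insert") {
      acceptanceInsert(rec$work[r], rec$bUsed[r], rec$NT[r], beta)
    } else {
      acceptanceDelete(rec$work[r], rec$bUsed[r], rec$N0[r], beta)
    }
  }, numeric(1))
  expect_equal(pRecomputed, rec$acceptanceProbability, tolerance = 1e-12)
  expect_identical(rec$accepted,
                   !rec$autoRejected & rec$rngDraw < pRecomputed)
})

test_that("a zero-cycle chain produces no trajectory and no records", {
  fx <- makeIdealGas(0)
  sched <- chainSchedule(0, "gas", nEquil = 0, rejectLimit = Inf)
  res <- runChain(fx$state, fx$region, sched,
                  list(gas = instantaneousProtocol()), c(gas = 0))
  expect_equal(nrow(res$records), 0)
  expect_equal(nrow(res$occupancy), 0)
  expect_length(res$frames, 0)
})

test_that("the chain stops after the consecutive-rejection limit", {
  set.seed(77)
  fx <- makeIdealGas(0, nInitial = 0)
  sched <- chainSchedule(5000, "gas", mdStepsPerCycle = 0, nEquil = 10,
                         rejectLimit = 200)
  ## B = -Inf: every insertion rejected, every deletion skipped
  res <- runChain(fx$state, fx$region, sched,
                  list(gas = instantaneousProtocol()), c(gas = -Inf))
  expect_true(res$terminatedEarly)
  post <- res$records$cycle > 10
  expect_equal(sum(post), 200)
  expect_false(any(res$records$accepted))
})

test_that("region counts are recomputed from geometry, not cached", {
  set.seed(78)
  fx <- makeIdealGas(0, boxEdge = 20, nInitial = 4)
  sphere <- gcmcRegion("sphere", center = c(10, 10, 10), radius = 5)
  n0 <- countInRegion(fx$state, sphere, "gas")
  ## teleport a molecule into the sphere: the count must follow immediately
  st <- placeMolecule(fx$state, 1, c(10, 10, 10))
  expect_equal(countInRegion(st, sphere, "gas"), n0 +
                 as.integer(sum((moleculeCenters(fx$state, 1) -
                                   c(10, 10, 10))^2) > 25))
  ## anchored region centres follow the anchor site
  anch <- gcmcRegion("sphere", radius = 3, anchor = 1)
  expect_equal(regionCenter(anch, st), c(10, 10, 10))
})

test_that("instantaneous sampling matches the exact grand-canonical weights", {
  set.seed(79)
  fx <- makeMeanFieldGas(b = 0, pairU = 0.9, boxEdge = 20)
  ## effectively a <= 4-state system: P(N >= 4) < 1e-5
  expect_lt(sum(fx$truth$dist$prob[fx$truth$dist$N >= 4]), 1e-4)
  sched <- chainSchedule(6000, "mf", mdStepsPerCycle = 1, nEquil = 500,
                         rejectLimit = Inf)
  res <- runChain(fx$state, fx$region, sched,
                  list(mf = instantaneousProtocol()), c(mf = 0))
  occ <- res$occupancy$mf[res$occupancy$cycle > 500]
  for (nState in 0:3) {
    freq <- mean(occ == nState)
    se <- blockedSE(as.numeric(occ == nState), 20)
    expect_lt(abs(freq - fx$truth$dist$prob[nState + 1]),
              3 * se + 0.02)
  }
})

test_that("detailed balance holds on an enumerable system (insert/delete flux)", {
  set.seed(80)
  ## single-occupancy well-free system truncated to N in {0,1}: the chain's
  ## stationary occupancy must match the two-state weights
  sp <- speciesSpec("x", epsilon = 0, mass = 40, pairConst = 1e6,
                    pairRange = Inf)
  sys <- toySystem(simulationBox(15), sp, temperature = 298)
  st <- systemState(sys, character(0))
  b <- log(2)  # P(1)/P(0) = exp(b) = 2
  sched <- chainSchedule(4000, "x", mdStepsPerCycle = 1, nEquil = 300,
                         rejectLimit = Inf)
  res <- runChain(st, gcmcRegion("whole_box"), sched,
                  list(x = instantaneousProtocol()), c(x = b))
  occ <- res$occupancy$x[res$occupancy$cycle > 300]
  expect_true(all(occ %in% 0:1))
  p1 <- exp(b) / (1 + exp(b))
  expect_lt(abs(mean(occ) - p1), 3 * blockedSE(occ, 20) + 0.02)
})
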