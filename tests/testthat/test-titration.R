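test_that("noiseless logistic data are refit to machine precision", {
  b50 <- -7.34; k <- 1
  bGrid <- seq(-11, -4, length.out = 12)
  syn <- makeSyntheticOccupancy(b50, k, bGrid, repeats = 2, noise = "none")
  fits <- fitBScale(syn$table)
  expect_true(all(fits$converged))
  expect_equal(fits$b50, rep(b50, 2), tolerance = 1e-6)
  expect_equal(fits$k, rep(k, 2), tolerance = 1e-6)
  ## occupancy on the fitted curve at the fitted B50 is exactly one half
  expect_equal(1 / (1 + exp(fits$k[1] * (fits$b50[1] - fits$b50[1]))), 0.5)
})

test_that("the log-concentration fit is an exact reparameterisation of the B fit", {
  spec <- adamsSpec(muEx = -2.5, temperature = 298, vGCMC = 2e4)
  syn <- makeSyntheticOccupancy(-6, 1.3, seq(-10, -2, length.out = 10),
                                repeats = 3, seed = 5, noise = "binomial")
  bFits <- fitBScale(syn$table)
  cFits <- fitLogcScale(syn$table, spec)
  expect_equal(cFits$kd, kdFromB50(spec, bFits$b50), tolerance = 1e-6)
  expect_true(all(cFits$kd > 0))
})

test_that("binomial-noise fits recover B50 within the repeat scatter", {
  b50 <- -5; k <- 1
  syn <- makeSyntheticOccupancy(b50, k, seq(-9, -1, length.out = 12),
                                nCycles = 100, repeats = 50, seed = 7)
  fits <- fitBScale(syn$table)
  ok <- fits[fits$converged, ]
  expect_gte(nrow(ok), 45)
  sem <- sd(ok$b50) / sqrt(nrow(ok))
  expect_lt(abs(mean(ok$b50) - b50), 3 * sem)
})

test_that("degenerate occupancy data are excluded with a warning", {
  tab <- data.frame(
    b = rep(seq(-2, 2, length.out = 6), 2),
    repeatId = rep(1:2, each = 6),
    occupancy = c(rep(0, 6), 1 / (1 + exp(seq(2, -2, length.out = 6)))),
    failed = FALSE
  )
  expect_warning(fits <- fitBScale(tab), "degenerate")
  expect_false(fits$converged[fits$repeatId == 1])
  expect_true(fits$converged[fits$repeatId == 2])
})

test_that("fits are invariant to row order and duplicated rows", {
  syn <- makeSyntheticOccupancy(-4, 0.8, seq(-8, 0, length.out = 10),
                                repeats = 1, seed = 3)
  f0 <- fitBScale(syn$table)
  shuffled <- syn$table[sample(nrow(syn$table)), ]
  f1 <- fitBScale(shuffled)
  expect_equal(f1$b50, f0$b50, tolerance = 1e-8)
  doubled <- rbind(syn$table, syn$table)
  f2 <- fitBScale(doubled)
  expect_equal(f2$b50, f0$b50, tolerance = 1e-8)
})

test_that("aggregation averages K_D across repeats with its standard error", {
  spec <- adamsSpec(0, 298, volumePerMolecule(1))  # B = ln(c) exactly
  fits <- data.frame(
    repeatId = 1:4,
    b50 = log(c(0.8, 1.0, 1.2, 1.0)), k = 1, converged = TRUE
  )
  tab <- data.frame(b = rep(seq(-3, 3, 1), 4),
                    repeatId = rep(1:4, each = 7),
                    occupancy = rep(1 / (1 + exp(-seq(-3, 3, 1))), 4))
  agg <- aggregateTitration(fits, spec, tab)
  kds <- c(0.8, 1.0, 1.2, 1.0)
  expect_equal(agg@kd, mean(kds), tolerance = 1e-10)
  expect_equal(agg@kdSe, sd(kds) / 2, tolerance = 1e-10)
  expect_equal(agg@dg, dgFromKd(mean(kds), 298), tolerance = 1e-12)
  ## perfectly monotone occupancy gives Kendall tau of 1
  expect_equal(agg@kendallTau, 1)
  ## identical repeats collapse the error to zero
  fitsSame <- transform(fits, b50 = 0)
  aggSame <- aggregateTitration(fitsSame, spec, tab)
  expect_equal(aggSame@kdSe, 0)
})

test_that("a full titration of the single-well toy recovers the enumerated truth", {
  fx <- makeSingleWell(depth = 4, width = 1, boxEdge = 10)
  bGrid <- fx$truth$b50 + seq(-2.5, 2.5, length.out = 6)
  sched <- chainSchedule(260, "ligand", mdStepsPerCycle = 3, nEquil = 60,
                         rejectLimit = 200, mdDtFs = 4)
  tab <- runTitration(fx$state, fx$region, sched, ncmcProtocol(6, 3, 4),
                      bGrid, repeats = 2, seed = 17)
  expect_equal(nrow(tab), 12)
  expect_false(any(tab$failed))
  ## occupancies rise with B and bracket the transition
  perB <- tapply(tab$occupancy, tab$b, mean)
  expect_lt(perB[1], 0.5)
  expect_gt(perB[length(perB)], 0.5)
  fits <- fitBScale(tab)
  agg <- aggregateTitration(fits, fx$spec, tab)
  ## short chains: require agreement within a generous multiple of the
  ## repeat scatter (the acceptance suite runs the full-length analogue)
  tol <- max(4 * agg@b50Se, 1)
  expect_lt(abs(agg@b50 - fx$truth$b50), tol)
  expect_gt(agg@kendallTau, 0.5)
})

test_that("synthetic occupancy generation validates its inputs", {
  expect_error(makeSyntheticOccupancy(-5, -1, 1:5), "k must be")
  syn <- makeSyntheticOccupancy(-5, 1, seq(-8, -2, 1), noise = "none")
  expect_equal(
    syn$table$occupancy[syn$table$repeatId == 1],
    1 / (1 + exp(syn$truth$b50 - seq(-8, -2, 1))),
    tolerance = 1e-12
  )
})
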