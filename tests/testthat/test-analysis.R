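## A static one-probe frame factory for grid tests.
staticFrames <- function(n, pos = c(5, 5, 5), boxEdge = 10,
                         present = rep(TRUE, n)) {
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(boxEdge), sp)
  lapply(seq_len(n), function(i) {
    if (present[i]) {
      systemState(sys, "probe", rbind(pos))
    } else {
      systemState(sys, character(0))
    }
  })
}

## Independent voxel-set oracle: centres within `radius` of any probe.
predictedVoxels <- function(points, spacing, radius, dims, origin = c(0, 0, 0)) {
  idx <- as.matrix(expand.grid(ix = 1:dims[1], iy = 1:dims[2],
                               iz = 1:dims[3]))
  ctr <- sweep((idx - 1) * spacing, 2, origin, "+")
  hit <- rep(FALSE, nrow(idx))
  for (r in seq_len(nrow(points))) {
    hit <- hit | rowSums(sweep(ctr, 2, points[r, ], "-")^2) <= radius^2
  }
  idx[hit, , drop = FALSE]
}

test_that("static probes occupy exactly the voxels within the capture radius", {
  frames <- staticFrames(4)
  g <- accumulateGrid(frames, spacing = 0.5, radius = 1.6)
  o <- gridOccupancy(g)
  want <- predictedVoxels(rbind(c(5, 5, 5)), 0.5, 1.6, g@dims)
  hit <- which(o == 1, arr.ind = TRUE)
  expect_equal(hit[order(hit[, 1], hit[, 2], hit[, 3]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                           drop = FALSE]),
               ignore_attr = TRUE)
  ## everything else is exactly zero
  expect_equal(sum(o > 0), nrow(want))
})

test_that("occupancy is the fraction of frames with a probe present", {
  frames <- staticFrames(10, present = c(rep(TRUE, 3), rep(FALSE, 7)))
  g <- accumulateGrid(frames, spacing = 0.5, radius = 1.6)
  o <- gridOccupancy(g)
  expect_equal(max(o), 0.3)
  expect_equal(o[11, 11, 11], 0.3)  # voxel at the probe position
})

test_that("two probes near one voxel still count once per frame", {
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(10), sp)
  fr <- systemState(sys, c("probe", "probe"), rbind(c(5, 5, 5), c(5.4, 5, 5)))
  g <- accumulateGrid(list(fr), spacing = 0.5, radius = 1.6)
  expect_equal(max(gridOccupancy(g)), 1)
  ## brute-force per-frame oracle: binary indicator, never 2
  expect_true(all(g@counts <= 1L))
})

test_that("ghost probes are excluded from grids", {
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(10), sp)
  fr <- systemState(sys, c("probe", "probe"), rbind(c(2, 2, 2), c(8, 8, 8)),
                    ghost = c(FALSE, TRUE))
  g <- accumulateGrid(list(fr), spacing = 0.5, radius = 1.6)
  o <- gridOccupancy(g)
  expect_equal(o[5, 5, 5], 1)    # voxel at (2,2,2)
  expect_equal(o[17, 17, 17], 0) # voxel at (8,8,8): ghost only
})

test_that("grid accumulation is order-independent over frames and probes", {
  set.seed(91)
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(10), sp)
  frames <- lapply(1:6, function(i) {
    systemState(sys, rep("probe", 3), matrix(runif(9) * 10, ncol = 3))
  })
  g1 <- accumulateGrid(frames)
  g2 <- accumulateGrid(rev(frames))
  expect_identical(g1@counts, g2@counts)
  ## probe order within a frame
  fr <- frames[[1]]
  frRev <- systemState(sys, rep("probe", 3),
                       moleculeCenters(fr)[3:1, ])
  expect_identical(accumulateGrid(list(fr))@counts,
                   accumulateGrid(list(frRev))@counts)
})

test_that("contouring returns thresholded voxel sets and components", {
  frames <- staticFrames(10, present = c(rep(TRUE, 4), rep(FALSE, 6)))
  g <- accumulateGrid(frames)
  ## occupancy is 0.4 everywhere near the probe
  expect_equal(contourReport(g, 0.3)$nComponents, 1)
  expect_equal(nrow(contourReport(g, 0.9)$voxels), 0)
  expect_equal(contourReport(g, 0.9)$nComponents, 0)
  ## threshold exactly at the maximum keeps the full within-radius set
  full <- contourReport(accumulateGrid(staticFrames(3)), 1.0)
  want <- predictedVoxels(rbind(c(5, 5, 5)), 0.5, 1.6,
                          accumulateGrid(staticFrames(1))@dims)
  expect_equal(nrow(full$voxels), nrow(want))
})

test_that("well-separated probes give two connected components with sane centroids", {
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(14), sp)
  fr <- systemState(sys, c("probe", "probe"), rbind(c(3, 3, 3), c(11, 11, 11)))
  g <- accumulateGrid(list(fr, fr))
  rep2 <- contourReport(g, 0.99)
  expect_equal(rep2$nComponents, 2)
  cen <- rep2$centroids[order(rep2$centroids[, 1]), ]
  expect_lt(max(abs(cen[1, ] - c(3, 3, 3))), 0.3)
  expect_lt(max(abs(cen[2, ] - c(11, 11, 11))), 0.3)
})

test_that("dihedral angles are computed with the standard sign convention", {
  ## trans butane-like: four points in a plane give pi
  expect_equal(abs(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                 c(1, -1, 0))), pi)
  ## cis: zero
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0)
  ## right-handed quarter turn
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 0, 1)), -pi / 2, tolerance = 1e-12)
})

test_that("dihedral binning reports fractions over assigned frames", {
  sp <- speciesSpec("lig", epsilon = 0)
  sys <- toySystem(simulationBox(12), sp)
  ctr <- c(6, 6, 6)
  refs <- list(ctr + c(0, 4, 4), ctr + c(0, 0, 4), ctr + c(0, 0, -4),
               list(species = "lig", site = 1))
  ## place the molecule at controlled azimuths: dihedral = atan2(-x, y)
  mkFrame <- function(theta) {
    pos <- ctr + 2 * c(cos(theta), sin(theta), 0)
    systemState(sys, "lig", rbind(pos))
  }
  ## all frames in one bin
  frames <- lapply(rep(0.5, 8), function(th) mkFrame(pi / 2 - th))
  dp <- dihedralPopulations(frames, refs, c(-pi, 0, pi))
  expect_equal(unname(dp@fractions), c(1, 0))
  ## uniform azimuths: fractions proportional to bin widths
  thetas <- seq(-pi + 1e-3, pi - 1e-3, length.out = 400)
  framesU <- lapply(thetas, mkFrame)
  edges <- c(-pi, -pi / 2, pi)
  dpU <- dihedralPopulations(framesU, refs, edges)
  expect_equal(unname(dpU@fractions), c(0.25, 0.75), tolerance = 0.02)
  expect_equal(sum(dpU@fractions), 1)
  ## frames without the molecule are skipped and counted
  framesM <- c(framesU[1:10], list(systemState(sys, character(0))))
  dpM <- dihedralPopulations(framesM, refs, edges)
  expect_equal(dpM@nSkipped, 1L)
})

test_that("pairwise-RMSD clustering recovers a 70/30 two-pose mixture", {
  set.seed(92)
  sp <- speciesSpec("lig", epsilon = 0)
  sys <- toySystem(simulationBox(12), sp)
  poseA <- c(3, 6, 6); poseB <- c(9, 6, 6)
  mk <- function(pos, jitter = 0) {
    systemState(sys, "lig", rbind(pos + rnorm(3, 0, jitter)))
  }
  frames <- c(lapply(1:70, function(i) mk(poseA)),
              lapply(1:30, function(i) mk(poseB)))
  cl <- rmsdModeClustering(frames, "lig", 2)
  expect_equal(sort(unname(cl@fractions)), c(0.3, 0.7))
  ## with small jitter the populations stay within 2%
  framesJ <- c(lapply(1:70, function(i) mk(poseA, 0.3)),
               lapply(1:30, function(i) mk(poseB, 0.3)))
  clJ <- rmsdModeClustering(framesJ, "lig", 2)
  expect_lt(max(abs(sort(unname(clJ@fractions)) - c(0.3, 0.7))), 0.02)
  expect_equal(dim(clJ@projection), c(100L, 2L))
  ## single pose: one cluster holds everything
  cl1 <- rmsdModeClustering(frames[1:20], "lig", 1)
  expect_equal(unname(cl1@fractions), 1)
  expect_error(rmsdModeClustering(frames[1:3], "lig", 5), "fewer frames")
})

test_that("dihedral binning and clustering agree on the two-pose fixture", {
  set.seed(93)
  sp <- speciesSpec("lig", epsilon = 0)
  sys <- toySystem(simulationBox(12), sp)
  ctr <- c(6, 6, 6)
  refs <- list(ctr + c(0, 4, 4), ctr + c(0, 0, 4), ctr + c(0, 0, -4),
               list(species = "lig", site = 1))
  mk <- function(x) {
    systemState(sys, "lig", rbind(ctr + c(x, 0, 0) + rnorm(3, 0, 0.2)))
  }
  frames <- c(lapply(1:65, function(i) mk(2.5)),
              lapply(1:35, function(i) mk(-2.5)))
  dp <- dihedralPopulations(frames, refs, c(-pi, 0, pi))
  cl <- rmsdModeClustering(frames, "lig", 2)
  expect_lt(max(abs(sort(unname(dp@fractions)) -
                      sort(unname(cl@fractions)))), 0.01)
})

test_that("Kabsch alignment removes an applied rigid transform", {
  set.seed(94)
  ref <- matrix(rnorm(30), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mobile <- sweep(ref %*% t(R), 2, c(2, -1, 5), "+")
  out <- kabschAlign(mobile, ref)
  expect_lt(out$rmsd, 1e-10)
})

test_that("empty trajectories and all-ghost frames are handled explicitly", {
  expect_error(accumulateGrid(list()), "empty")
  sp <- speciesSpec("probe", epsilon = 0)
  sys <- toySystem(simulationBox(10), sp)
  fr <- systemState(sys, "probe", rbind(c(5, 5, 5)), ghost = TRUE)
  expect_warning(g <- accumulateGrid(list(fr)), "no real probe")
  expect_equal(sum(g@counts), 0L)
})
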