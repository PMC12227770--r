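## Post-hoc trajectory analytics: occupancy grids for site mapping, and
## binding-mode populations via dihedral binning and pairwise-RMSD
## clustering. Frames are SystemState snapshots (e.g. from runChain); toy
## systems have a fixed laboratory frame, so no alignment is applied here --
## kabschAlign is available for externally supplied trajectories.

## Real (non-ghost) site positions of a frame, optionally species-filtered.
.probeSites <- function(frame, species = NULL) {
  m <- frame@molecules
  keep <- !frame@ghost
  if (!is.null(species)) keep <- keep & m$species == species
  idx <- which(keep)
  if (!length(idx)) return(matrix(0, 0, 3))
  rows <- unlist(lapply(idx, function(i) m$start[i]:m$end[i]))
  frame@positions[rows, , drop = FALSE]
}

#' Accumulate an occupancy grid over a trajectory
#'
#' Builds a regular voxel grid (default 0.5 angstrom spacing) and, for each
#' frame, marks every voxel whose centre lies within the capture radius
#' (default 1.6 angstrom) of any real probe site. A voxel counts at most
#' once per frame regardless of how many probes are near it; the average
#' occupancy is counts / nFrames.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param spacing Voxel spacing (angstrom).
#' @param radius Capture radius (angstrom).
#' @param species Optional species filter for the probes.
#' @param origin,dims Optional grid origin and integer extents; default
#'   covers the simulation box.
#' @return An \linkS4class{OccupancyGrid}.
#' @export
accumulateGrid <- function(frames, spacing = 0.5, radius = 1.6,
                           species = NULL, origin = NULL, dims = NULL) {
  if (!length(frames)) stop("empty trajectory")
  box <- frames[[1]]@system@box
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (is.null(dims)) dims <- as.integer(floor(box@edge / spacing)) + 1L
  dims <- as.integer(dims)
  counts <- array(0L, dims)
  sawProbe <- FALSE
  for (fr in frames) {
    sites <- .probeSites(fr, species)
    if (!nrow(sites)) next
    sawProbe <- TRUE
    occ <- array(FALSE, dims)
    for (s in seq_len(nrow(sites))) {
      occ <- .markVoxels(occ, sites[s, ], origin, spacing, radius, dims)
    }
    counts <- counts + occ
  }
  if (!sawProbe) warning("no real probe sites in any frame; grid is zero")
  new("OccupancyGrid",
    origin = as.numeric(origin), spacing = spacing, dims = dims,
    counts = counts, nFrames = length(frames), radius = radius
  )
}

## Mark voxels within `radius` of point p (no periodic wrapping; analysis
## grids live in the laboratory frame).
.markVoxels <- function(occ, p, origin, spacing, radius, dims) {
  lo <- pmax(1L, as.integer(ceiling((p - radius - origin) / spacing)) + 1L)
  hi <- pmin(dims, as.integer(floor((p + radius - origin) / spacing)) + 1L)
  if (any(lo > hi)) return(occ)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- origin[1] + (ix - 1) * spacing
  cy <- origin[2] + (iy - 1) * spacing
  cz <- origin[3] + (iz - 1) * spacing
  dx2 <- (cx - p[1])^2
  dy2 <- (cy - p[2])^2
  dz2 <- (cz - p[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  hit <- r2 <= radius^2
  occ[ix, iy, iz] <- occ[ix, iy, iz, drop = FALSE] | hit
  occ
}

#' Average-occupancy values of a grid
#'
#' @param grid An \linkS4class{OccupancyGrid}.
#' @return 3-d numeric array counts / nFrames.
#' @export
gridOccupancy <- function(grid) {
  if (grid@nFrames == 0L) return(grid@counts * 0)
  grid@counts / grid@nFrames
}

#' Contour an occupancy grid at a threshold
#'
#' Selects voxels with average occupancy >= threshold and labels their
#' connected components (26-neighbourhood).
#'
#' @param grid An \linkS4class{OccupancyGrid}.
#' @param threshold Occupancy threshold in (0, 1].
#' @return List with voxels (data.frame ix, iy, iz, occupancy, component,
#'   x, y, z), nComponents, and centroids (one row per component).
#' @export
contourReport <- function(grid, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  o <- gridOccupancy(grid)
  sel <- which(o >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) {
    return(list(
      voxels = data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                          occupancy = numeric(0), component = integer(0),
                          x = numeric(0), y = numeric(0), z = numeric(0)),
      nComponents = 0L, centroids = matrix(0, 0, 3)
    ))
  }
  comp <- .connectedComponents(sel)
  xyz <- sweep((sel - 1) * grid@spacing, 2, grid@origin, "+")
  vox <- data.frame(
    ix = sel[, 1], iy = sel[, 2], iz = sel[, 3],
    occupancy = o[sel], component = comp,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  nC <- max(comp)
  centroids <- t(vapply(seq_len(nC), function(k) {
    colMeans(xyz[comp == k, , drop = FALSE])
  }, numeric(3)))
  list(voxels = vox, nComponents = nC, centroids = centroids)
}

## Label connected components of voxel index rows (26-neighbourhood) by
## breadth-first search on a hashed index set.
.connectedComponents <- function(idx) {
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- stats::setNames(seq_len(n), key)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- sweep(nbr, 2, as.numeric(idx[v, ]), "+")
      hits <- lookup[paste(nb[, 1], nb[, 2], nb[, 3])]
      hits <- hits[!is.na(hits)]
      new <- hits[comp[hits] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Length-3 coordinates.
#' @return Angle in (-pi, pi].
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

## Resolve a site reference against a frame: a length-3 numeric is a fixed
## anchor; list(species=, site=) picks a site of the first real molecule of
## that species (NULL when absent).
.resolveSite <- function(frame, ref) {
  if (is.numeric(ref) && length(ref) == 3L) return(as.numeric(ref))
  stopifnot(is.list(ref), !is.null(ref$species))
  m <- frame@molecules
  idx <- which(!frame@ghost & m$species == ref$species)
  if (!length(idx)) return(NULL)
  i <- idx[1]
  siteNo <- if (is.null(ref$site)) 1L else as.integer(ref$site)
  as.numeric(frame@positions[m$start[i] + siteNo - 1L, ])
}

#' Binding-mode populations from a dihedral angle
#'
#' Computes the signed dihedral over four site references per frame and bins
#' it with the user's edges. Frames in which any molecular reference is
#' absent (molecule deleted) are skipped and counted.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param siteRefs List of four references: fixed length-3 anchors or
#'   list(species =, site =) molecular sites.
#' @param binEdges Increasing numeric vector of bin edges within (-pi, pi].
#' @return A \linkS4class{ModePopulations} (method "dihedral"); bin labels
#'   are the integer bin indices.
#' @export
dihedralPopulations <- function(frames, siteRefs, binEdges) {
  stopifnot(length(siteRefs) == 4L, length(binEdges) >= 2L)
  angles <- numeric(0)
  skipped <- 0L
  for (fr in frames) {
    pts <- lapply(siteRefs, .resolveSite, frame = fr)
    if (any(vapply(pts, is.null, logical(1)))) {
      skipped <- skipped + 1L
      next
    }
    angles <- c(angles, dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
  }
  lab <- findInterval(angles, binEdges, rightmost.closed = TRUE)
  keep <- lab >= 1L & lab < length(binEdges)
  lab <- as.integer(lab[keep])
  nBins <- length(binEdges) - 1L
  counts <- tabulate(lab, nbins = nBins)
  names(counts) <- paste0("bin", seq_len(nBins))
  fr <- if (sum(counts)) counts / sum(counts) else counts * 0
  new("ModePopulations",
    labels = lab, counts = as.integer(counts), fractions = fr,
    nSkipped = skipped + as.integer(sum(!keep)), method = "dihedral",
    projection = NULL
  )
}

#' Binding-mode populations from pairwise-RMSD clustering
#'
#' Collects the site coordinates of the (first) real molecule of a species
#' per frame, computes the pairwise RMSD matrix without additional
#' superposition, clusters it with average-linkage hierarchical clustering
#' cut at the requested number of modes, and projects the distances to two
#' dimensions by classical multidimensional scaling for plotting.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param species Species whose molecule is clustered.
#' @param nModes Number of modes to cut the tree at.
#' @return A \linkS4class{ModePopulations} (method "rmsd") with a projection
#'   matrix.
#' @export
rmsdModeClustering <- function(frames, species, nModes) {
  coords <- list()
  skipped <- 0L
  for (fr in frames) {
    m <- fr@molecules
    idx <- which(!fr@ghost & m$species == species)
    if (!length(idx)) {
      skipped <- skipped + 1L
      next
    }
    i <- idx[1]
    coords[[length(coords) + 1L]] <-
      fr@positions[m$start[i]:m$end[i], , drop = FALSE]
  }
  nF <- length(coords)
  if (nF < 2L) stop("need at least 2 bound frames")
  if (nModes > nF) stop("fewer frames than requested modes")
  nSites <- nrow(coords[[1]])
  flat <- t(vapply(coords, function(x) as.numeric(x), numeric(3 * nSites)))
  ## RMSD between frames = euclidean distance of flattened coords / sqrt(n)
  d <- stats::dist(flat) / sqrt(nSites)
  lab <- stats::cutree(stats::hclust(d, method = "average"), k = nModes)
  counts <- tabulate(lab, nbins = nModes)
  names(counts) <- paste0("mode", seq_len(nModes))
  proj <- if (nF > 2L) {
    suppressWarnings(stats::cmdscale(d, k = 2))
  } else {
    matrix(0, nF, 2)
  }
  proj <- as.matrix(proj)
  while (ncol(proj) < 2L) proj <- cbind(proj, 0)  # degenerate geometries
  proj <- proj[, 1:2, drop = FALSE]
  new("ModePopulations",
    labels = as.integer(lab), counts = as.integer(counts),
    fractions = counts / sum(counts), nSkipped = skipped, method = "rmsd",
    projection = proj
  )
}

#' Select frames whose molecule lies near given centres
#'
#' Keeps the frames in which the centre of geometry of the (first) real
#' molecule of a species lies within \code{radius} of any of the supplied
#' centres -- e.g. the bound frames of a binding-site trajectory.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param species Species name.
#' @param centers m x 3 matrix (or length-3 vector) of centres.
#' @param radius Capture radius (angstrom).
#' @return The filtered list of frames.
#' @export
framesNearCenters <- function(frames, species, centers, radius) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  Filter(function(fr) {
    m <- fr@molecules
    idx <- which(!fr@ghost & m$species == species)
    if (!length(idx)) return(FALSE)
    cog <- as.numeric(moleculeCenters(fr, idx[1]))
    d2 <- rowSums(sweep(centers, 2, cog, "-")^2)
    any(d2 <= radius^2)
  }, frames)
}

#' Rigid-body least-squares alignment (Kabsch)
#'
#' Aligns a mobile coordinate set onto a reference by the optimal rotation
#' and translation; for externally supplied trajectories (toy systems have a
#' fixed laboratory frame and do not need alignment).
#'
#' @param mobile,ref n x 3 coordinate matrices.
#' @return List with coords (aligned mobile), rotation, rmsd.
#' @export
kabschAlign <- function(mobile, ref) {
  stopifnot(identical(dim(mobile), dim(ref)), ncol(mobile) == 3L)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  out <- sweep(A %*% t(R), 2, cr, "+")
  list(
    coords = out, rotation = R,
    rmsd = sqrt(mean(rowSums((out - ref)^2)))
  )
}
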