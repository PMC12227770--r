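## Configuration loading/validation and the plain-text format writers.
##
## Run configurations are YAML with explicit defaults; unknown keys are
## fatal so typos cannot silently fall back to defaults. All writers are
## bit-stable given identical inputs.

.configDefaults <- list(
  temperature = 298, cutoff = 12, coulomb = FALSE,
  analysis = list(spacing = 0.5, radius = 1.6),
  schedule = list(
    n_cycles = 1700L, md_steps_per_cycle = 10L, n_equil = 200L,
    reject_limit = 200, md_dt_fs = 2, friction = 1
  ),
  protocol = list(n_pert = 99L, n_prop = 10L, dt_fs = 2, alpha = 0.5,
                  stage_split = 0.5)
)

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  x
}

.fillDefaults <- function(x, defaults) {
  for (k in names(defaults)) {
    if (is.null(x[[k]])) {
      x[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(x[[k]])) {
      x[[k]] <- .fillDefaults(x[[k]], defaults[[k]])
    }
  }
  x
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, applies the
#' documented defaults (temperature 298 K, cutoff 12 A, grid spacing 0.5 A,
#' capture radius 1.6 A, 200 equilibration cycles, reject limit 200) and
#' validates value ranges.
#'
#' @param path Path to a YAML file.
#' @return Normalised configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, c(
    "temperature", "cutoff", "coulomb", "box", "species", "wells", "region",
    "protocol", "schedule", "analysis", "initial", "adams"
  ), "config")
  cfg <- .fillDefaults(cfg, .configDefaults)
  if (is.null(cfg$box)) stop("config needs a 'box' block")
  .checkKeys(cfg$box, c("edge", "periodic"), "box")
  if (is.null(cfg$box$periodic)) cfg$box$periodic <- TRUE
  if (is.null(cfg$species) || !length(cfg$species)) {
    stop("config needs at least one species")
  }
  cfg$species <- lapply(cfg$species, function(s) {
    .checkKeys(s, c("name", "epsilon", "sigma", "charge", "mass",
                    "pair_const", "pair_range", "site_coords"), "species")
    .fillDefaults(s, list(epsilon = 0, sigma = 3.4, charge = 0, mass = 40,
                          pair_const = 0, pair_range = Inf))
  })
  cfg$wells <- lapply(cfg$wells, function(w) {
    w <- .checkKeys(w, c("center", "depth", "width", "form", "species"),
                    "wells")
    w <- .fillDefaults(w, list(form = "gaussian", species = ""))
    if (w$depth < 0) stop("well depth must be >= 0")
    if (w$width <= 0) stop("well width must be > 0")
    w
  })
  if (!is.null(cfg$region)) {
    .checkKeys(cfg$region, c("mode", "center", "radius", "anchor"), "region")
    if (identical(cfg$region$mode, "sphere") &&
        (is.null(cfg$region$radius) || cfg$region$radius <= 0)) {
      stop("sphere region needs a positive radius")
    }
  }
  .checkKeys(cfg$protocol, c("n_pert", "n_prop", "dt_fs", "alpha",
                             "stage_split"), "protocol")
  .checkKeys(cfg$schedule, c("n_cycles", "md_steps_per_cycle", "n_equil",
                             "reject_limit", "md_dt_fs", "friction",
                             "move_pattern"), "schedule")
  .checkKeys(cfg$analysis, c("spacing", "radius"), "analysis")
  if (cfg$schedule$n_cycles > 0 &&
      cfg$schedule$n_equil >= cfg$schedule$n_cycles) {
    stop("schedule: n_equil (", cfg$schedule$n_equil,
         ") must be smaller than n_cycles (", cfg$schedule$n_cycles, ")")
  }
  if (cfg$analysis$radius <= 0) stop("analysis radius must be > 0")
  if (cfg$analysis$spacing <= 0) stop("analysis spacing must be > 0")
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  cfg
}

#' Write a configuration back to YAML
#'
#' @param cfg Configuration list (as from \code{\link{loadConfig}}).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build simulation objects from a configuration
#'
#' @param cfg Configuration list from \code{\link{loadConfig}}.
#' @return List with system, state, region, protocol, schedule.
#' @export
buildFromConfig <- function(cfg) {
  box <- simulationBox(cfg$box$edge, cfg$box$periodic)
  species <- lapply(cfg$species, function(s) {
    speciesSpec(
      s$name,
      siteCoords = if (is.null(s$site_coords)) matrix(0, 1, 3) else
        do.call(rbind, s$site_coords),
      epsilon = s$epsilon, sigma = s$sigma, charge = s$charge,
      mass = s$mass, pairConst = s$pair_const, pairRange = s$pair_range
    )
  })
  wells <- lapply(cfg$wells, function(w) {
    bindingWell(w$center, w$depth, w$width, w$form, w$species)
  })
  sys <- toySystem(box, species, wells, cfg$temperature, cfg$cutoff,
                   isTRUE(cfg$coulomb))
  region <- if (is.null(cfg$region)) {
    gcmcRegion("whole_box")
  } else if (identical(cfg$region$mode, "sphere")) {
    gcmcRegion("sphere",
               center = if (is.null(cfg$region$center)) box@edge / 2 else
                 cfg$region$center,
               radius = cfg$region$radius,
               anchor = cfg$region$anchor)
  } else {
    gcmcRegion("whole_box")
  }
  protocol <- ncmcProtocol(
    cfg$protocol$n_pert, cfg$protocol$n_prop, cfg$protocol$dt_fs,
    alpha = cfg$protocol$alpha, stageSplit = cfg$protocol$stage_split
  )
  pattern <- cfg$schedule$move_pattern
  if (is.null(pattern)) pattern <- cfg$species[[1]]$name
  schedule <- chainSchedule(
    cfg$schedule$n_cycles, unlist(pattern),
    cfg$schedule$md_steps_per_cycle, cfg$schedule$n_equil,
    cfg$schedule$reject_limit, cfg$schedule$md_dt_fs, cfg$schedule$friction
  )
  speciesNames <- character(0)
  centers <- matrix(0, 0, 3)
  for (ini in cfg$initial) {
    n <- if (is.null(ini$n)) 1L else as.integer(ini$n)
    speciesNames <- c(speciesNames, rep(ini$species, n))
    centers <- rbind(centers, matrix(stats::runif(3 * n) * box@edge,
                                     ncol = 3))
  }
  state <- systemState(sys, speciesNames, centers)
  list(system = sys, state = state, region = region, protocol = protocol,
       schedule = schedule)
}

#' Write frames as an XYZ trajectory
#'
#' All sites are written (ghosts included); the comment line records the
#' frame index and the number of real molecules.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTrajectoryXYZ <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!length(frames)) {
    warning("empty frame list; writing header-only file")
    writeLines("0", con)
    writeLines("frame=0 nreal=0", con)
    return(invisible(path))
  }
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    m <- fr@molecules
    writeLines(as.character(nrow(fr@positions)), con)
    writeLines(sprintf("frame=%d nreal=%d", i, sum(!fr@ghost)), con)
    for (j in seq_len(nrow(m))) {
      rows <- m$start[j]:m$end[j]
      for (r in rows) {
        writeLines(sprintf("%s %.6f %.6f %.6f", m$species[j],
                           fr@positions[r, 1], fr@positions[r, 2],
                           fr@positions[r, 3]), con)
      }
    }
  }
  invisible(path)
}

#' Write frames as a minimal multi-model PDB
#'
#' Ghost molecules are written with occupancy 0.00, real molecules with
#' 1.00.
#'
#' @param frames List of \linkS4class{SystemState} snapshots.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTrajectoryPDB <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!length(frames)) {
    warning("empty frame list; writing header-only file")
    writeLines("END", con)
    return(invisible(path))
  }
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    m <- fr@molecules
    writeLines(sprintf("MODEL     %4d", i), con)
    serial <- 0L
    for (j in seq_len(nrow(m))) {
      occ <- if (fr@ghost[j]) 0 else 1
      for (r in m$start[j]:m$end[j]) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, substr(toupper(m$species[j]), 1, 4),
          substr(toupper(m$species[j]), 1, 3), j,
          fr@positions[r, 1], fr@positions[r, 2], fr@positions[r, 3],
          occ, 0
        ), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an occupancy grid in OpenDX format
#'
#' Standard OpenDX scalar-field layout (gridpositions, gridconnections,
#' data array with the z index fastest), with the origin, spacing and
#' counts in the header.
#'
#' @param grid An \linkS4class{OccupancyGrid}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeGridDX <- function(grid, path) {
  o <- gridOccupancy(grid)
  d <- grid@dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f", grid@origin[1],
                     grid@origin[2], grid@origin[3]), con)
  writeLines(sprintf("delta %.6f 0.000000 0.000000", grid@spacing), con)
  writeLines(sprintf("delta 0.000000 %.6f 0.000000", grid@spacing), con)
  writeLines(sprintf("delta 0.000000 0.000000 %.6f", grid@spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)
  ), con)
  ## x slowest, z fastest per the OpenDX convention
  vals <- as.numeric(aperm(o, c(3, 2, 1)))
  lines <- vapply(
    split(vals, ceiling(seq_along(vals) / 3)),
    function(v) paste(sprintf("%.6g", v), collapse = " "),
    character(1)
  )
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "occupancy" class field', con)
  invisible(path)
}

#' Read an OpenDX occupancy grid
#'
#' Reads files written by \code{\link{writeGridDX}} back into an
#' \linkS4class{OccupancyGrid} (counts are reconstructed from occupancies
#' scaled by nFrames = 1, so only the occupancy values round-trip).
#'
#' @param path Path to a DX file.
#' @return List with origin, spacing, dims, values (3-d array).
#' @export
readGridDX <- function(path) {
  lines <- readLines(path)
  cts <- regmatches(lines[1], gregexpr("[0-9]+", lines[1]))[[1]]
  dims <- as.integer(cts[2:4])
  org <- as.numeric(strsplit(trimws(sub("origin", "", lines[2])), " +")[[1]])
  sp <- as.numeric(strsplit(trimws(sub("delta", "", lines[3])), " +")[[1]])[1]
  dataStart <- grep("data follows", lines)[1] + 1L
  dataEnd <- grep("attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[dataStart:dataEnd]), " +")))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  list(origin = org, spacing = sp, dims = dims, values = arr)
}

#' Write a data frame as CSV
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTable <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
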