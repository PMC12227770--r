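#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Periodic simulation box
#'
#' An orthorhombic box with per-axis periodicity flags. The box volume is the
#' product of the edge lengths.
#'
#' @slot edge Numeric length-3 vector of edge lengths (angstrom).
#' @slot periodic Logical length-3 vector; TRUE for periodic axes.
#' @export
setClass("SimulationBox",
  representation(edge = "numeric", periodic = "logical"),
  prototype(edge = c(20, 20, 20), periodic = c(TRUE, TRUE, TRUE))
)

setValidity("SimulationBox", function(object) {
  if (length(object@edge) != 3L || any(!is.finite(object@edge)) ||
      any(object@edge <= 0)) {
    return("edge must be three positive finite lengths")
  }
  if (length(object@periodic) != 3L) return("periodic must be length 3")
  TRUE
})

#' Rigid molecular species
#'
#' A rigid multi-site molecule with per-site Lennard-Jones parameters, partial
#' charges and masses, plus an optional square-well pair term acting between
#' the centres of geometry of molecules of the same species. The pair term
#' (constant energy \code{pairConst} inside range \code{pairRange}) supports
#' the analytically enumerable toys: with infinite range it gives a mean-field
#' pair energy; with a large positive constant and a short range it implements
#' single-occupancy exclusion in a binding site.
#'
#' @slot name Species identifier.
#' @slot siteCoords n x 3 matrix of site coordinates in the molecule frame
#'   (angstrom); a single-site species has one zero row.
#' @slot epsilon Per-site LJ well depth (kcal/mol), zero for ideal sites.
#' @slot sigma Per-site LJ diameter (angstrom), must be positive.
#' @slot charge Per-site partial charge (e).
#' @slot mass Per-site mass (amu).
#' @slot pairConst Constant same-species pair energy (kcal/mol), default 0.
#' @slot pairRange Range of the constant pair term (angstrom), may be Inf.
#' @export
setClass("SpeciesSpec",
  representation(
    name = "character", siteCoords = "matrix", epsilon = "numeric",
    sigma = "numeric", charge = "numeric", mass = "numeric",
    pairConst = "numeric", pairRange = "numeric"
  ),
  prototype(pairConst = 0, pairRange = Inf)
)

setValidity("SpeciesSpec", function(object) {
  n <- nrow(object@siteCoords)
  if (is.null(n) || n < 1L || ncol(object@siteCoords) != 3L) {
    return("siteCoords must be an n x 3 matrix with n >= 1")
  }
  for (s in c("epsilon", "sigma", "charge", "mass")) {
    if (length(slot(object, s)) != n) {
      return(sprintf("%s must have one value per site", s))
    }
  }
  if (any(object@sigma <= 0)) return("sigma must be positive")
  if (any(object@epsilon < 0)) return("epsilon must be non-negative")
  if (any(object@mass <= 0)) return("mass must be positive")
  if (length(object@name) != 1L || !nzchar(object@name)) {
    return("name must be a non-empty string")
  }
  TRUE
})

#' External binding well
#'
#' A smooth attractive well standing in for a protein pocket. The gaussian
#' form is U(r) = -depth * exp(-r^2 / (2 width^2)); the square form is
#' U(r) = -depth for r <= width and 0 beyond (enumeration tests only, as its
#' force is discontinuous).
#'
#' @slot center Numeric length-3 well centre (angstrom).
#' @slot depth Well depth (kcal/mol), >= 0.
#' @slot width Length scale (angstrom), > 0.
#' @slot form Either "gaussian" or "square".
#' @slot species Name of the species the well acts on ("" for all).
#' @export
setClass("BindingWell",
  representation(
    center = "numeric", depth = "numeric", width = "numeric",
    form = "character", species = "character"
  ),
  prototype(form = "gaussian", species = "")
)

setValidity("BindingWell", function(object) {
  if (length(object@center) != 3L) return("center must be length 3")
  if (object@depth < 0) return("depth must be >= 0")
  if (object@width <= 0) return("width must be > 0")
  if (!object@form %in% c("gaussian", "square")) {
    return("form must be 'gaussian' or 'square'")
  }
  TRUE
})

#' Toy particle system definition
#'
#' Immutable description of a toy system: the box, the available species, any
#' external binding wells, the thermostat temperature and the nonbonded
#' cutoff. Coulomb interactions (cutoff-truncated) are evaluated only when
#' \code{coulomb} is TRUE.
#'
#' @slot box A \linkS4class{SimulationBox}.
#' @slot species Named list of \linkS4class{SpeciesSpec} objects.
#' @slot wells List of \linkS4class{BindingWell} objects (possibly empty).
#' @slot temperature Thermostat temperature (K).
#' @slot cutoff Nonbonded cutoff (angstrom); default 12.
#' @slot coulomb Logical; evaluate truncated Coulomb terms.
#' @export
setClass("ToySystem",
  representation(
    box = "SimulationBox", species = "list", wells = "list",
    temperature = "numeric", cutoff = "numeric", coulomb = "logical"
  ),
  prototype(wells = list(), temperature = 298, cutoff = 12, coulomb = FALSE)
)

setValidity("ToySystem", function(object) {
  if (length(object@species) < 1L) return("at least one species required")
  if (is.null(names(object@species)) || any(!nzchar(names(object@species)))) {
    return("species list must be named")
  }
  ok <- vapply(object@species, is, logical(1), class2 = "SpeciesSpec")
  if (!all(ok)) return("species must be SpeciesSpec objects")
  okw <- vapply(object@wells, is, logical(1), class2 = "BindingWell")
  if (length(okw) && !all(okw)) return("wells must be BindingWell objects")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Instantaneous state of a toy system
#'
#' Site positions and velocities for all molecules, real and ghost. Ghost
#' molecules are fully decoupled: they contribute no energy, feel no force and
#' are excluded from kinetic-energy accounting; they are parked in place so
#' that insertion moves can couple them without changing array topology.
#'
#' @slot system The \linkS4class{ToySystem} definition.
#' @slot positions nSites x 3 matrix of site positions (angstrom), wrapped
#'   into the primary box image on periodic axes.
#' @slot velocities nSites x 3 matrix of site velocities (angstrom/ps).
#' @slot molecules data.frame with columns species (character), start, end
#'   (site index range per molecule).
#' @slot ghost Logical per-molecule ghost flag.
#' @export
setClass("SystemState",
  representation(
    system = "ToySystem", positions = "matrix", velocities = "matrix",
    molecules = "data.frame", ghost = "logical"
  )
)

setValidity("SystemState", function(object) {
  np <- nrow(object@positions)
  if (ncol(object@positions) != 3L) return("positions must be n x 3")
  if (!identical(dim(object@velocities), dim(object@positions))) {
    return("velocities must match positions in shape")
  }
  m <- object@molecules
  need <- c("species", "start", "end")
  if (!all(need %in% names(m))) {
    return("molecules needs columns species, start, end")
  }
  if (nrow(m) != length(object@ghost)) {
    return("ghost must have one flag per molecule")
  }
  if (nrow(m)) {
    if (any(m$start > m$end) || min(m$start) < 1L || max(m$end) > np) {
      return("molecule site ranges out of bounds")
    }
    covered <- sum(m$end - m$start + 1L)
    if (covered != np) return("molecule site ranges must tile positions")
    if (!all(m$species %in% names(object@system@species))) {
      return("unknown species in molecule table")
    }
  } else if (np != 0L) {
    return("positions present without molecules")
  }
  TRUE
})

#' Nonequilibrium switching protocol
#'
#' Defines one alchemical switch: nPert perturbation steps between the
#' decoupled and coupled end states, nProp thermostatted MD steps between
#' perturbations, the integrator time step, the soft-core alpha and the
#' fraction of the lambda path devoted to the Lennard-Jones stage. The
#' switching time is tau = (nPert + 1) * nProp * dt.
#'
#' @slot nPert Number of perturbation steps (>= 1).
#' @slot nProp MD propagation steps per perturbation (>= 1).
#' @slot dtFs Integrator time step (fs).
#' @slot direction "insert" or "delete".
#' @slot alpha Soft-core parameter (dimensionless), default 0.5.
#' @slot stageSplit Fraction of perturbations in the LJ stage for an
#'   insertion (electrostatics staged after); default 0.5.
#' @export
setClass("NCMCProtocol",
  representation(
    nPert = "integer", nProp = "integer", dtFs = "numeric",
    direction = "character", alpha = "numeric", stageSplit = "numeric"
  ),
  prototype(direction = "insert", alpha = 0.5, stageSplit = 0.5)
)

setValidity("NCMCProtocol", function(object) {
  if (object@nPert < 1L) return("nPert must be >= 1")
  if (object@nProp < 1L) return("nProp must be >= 1")
  if (object@dtFs <= 0) return("dtFs must be > 0")
  if (!object@direction %in% c("insert", "delete")) {
    return("direction must be 'insert' or 'delete'")
  }
  if (object@alpha < 0) return("alpha must be >= 0")
  if (object@stageSplit <= 0 || object@stageSplit > 1) {
    return("stageSplit must be in (0, 1]")
  }
  TRUE
})

#' GCMC region
#'
#' The region targeted by insertion/deletion moves: either a sphere (fixed
#' centre or anchored to a site index, re-evaluated at every membership
#' query) or the whole box.
#'
#' @slot mode "sphere" or "whole_box".
#' @slot center Numeric length-3 sphere centre (angstrom); ignored when
#'   anchored or in whole_box mode.
#' @slot anchor Site index whose current position defines the centre, or NULL.
#' @slot radius Sphere radius (angstrom).
#' @export
setClass("GCMCRegion",
  representation(
    mode = "character", center = "numeric", anchor = "numericOrNULL",
    radius = "numeric"
  ),
  prototype(mode = "whole_box", center = c(0, 0, 0), anchor = NULL, radius = 0)
)

setValidity("GCMCRegion", function(object) {
  if (!object@mode %in% c("sphere", "whole_box")) {
    return("mode must be 'sphere' or 'whole_box'")
  }
  if (object@mode == "sphere") {
    if (object@radius <= 0) return("sphere radius must be > 0")
    if (is.null(object@anchor) && length(object@center) != 3L) {
      return("sphere needs a centre or an anchor")
    }
  }
  TRUE
})

#' Adams-value specification
#'
#' Everything needed to convert between Adams value, concentration, K_D and
#' standard binding free energy: the excess chemical potential of the species
#' in the reference solution (with its standard error), the temperature and
#' the GCMC region volume. The standard-state volume is derived as
#' 1/(cStandard * N_A).
#'
#' @slot muEx Excess chemical potential (kcal/mol).
#' @slot muExSe Standard error on muEx (kcal/mol).
#' @slot temperature Temperature (K).
#' @slot vGCMC GCMC region volume (angstrom^3).
#' @slot cStandard Standard-state concentration (mol/L), default 1.
#' @export
setClass("AdamsSpec",
  representation(
    muEx = "numeric", muExSe = "numeric", temperature = "numeric",
    vGCMC = "numeric", cStandard = "numeric"
  ),
  prototype(muExSe = 0, cStandard = 1)
)

setValidity("AdamsSpec", function(object) {
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@vGCMC <= 0) return("vGCMC must be > 0")
  if (object@cStandard <= 0) return("cStandard must be > 0")
  if (object@muExSe < 0) return("muExSe must be >= 0")
  TRUE
})

#' Chain schedule for GCNCMC/MD
#'
#' One cycle is a stretch of MD followed by one GCNCMC move per entry of the
#' species move pattern. The first nEquil cycles are discarded as
#' equilibration by downstream analysis; after equilibration the chain stops
#' early once rejectLimit consecutive moves have been rejected.
#'
#' @slot mdStepsPerCycle MD steps between move blocks.
#' @slot movePattern Character vector of species names, one move each per
#'   cycle.
#' @slot nCycles Total number of cycles.
#' @slot nEquil Equilibration cycles discarded downstream.
#' @slot rejectLimit Consecutive-rejection stop limit (Inf to disable).
#' @slot mdDtFs MD time step (fs).
#' @slot friction Langevin friction (1/ps).
#' @export
setClass("ChainSchedule",
  representation(
    mdStepsPerCycle = "integer", movePattern = "character",
    nCycles = "integer", nEquil = "integer", rejectLimit = "numeric",
    mdDtFs = "numeric", friction = "numeric"
  ),
  prototype(
    mdStepsPerCycle = 10L, nEquil = 200L, rejectLimit = 200,
    mdDtFs = 2, friction = 1
  )
)

setValidity("ChainSchedule", function(object) {
  if (object@nCycles < 0L) return("nCycles must be >= 0")
  if (object@nCycles > 0L && object@nEquil >= object@nCycles) {
    return("nEquil must be < nCycles")
  }
  if (object@mdStepsPerCycle < 0L) return("mdStepsPerCycle must be >= 0")
  if (object@rejectLimit <= 0) return("rejectLimit must be > 0 (or Inf)")
  if (object@mdDtFs <= 0 || object@friction < 0) {
    return("mdDtFs must be > 0 and friction >= 0")
  }
  TRUE
})

#' Occupancy grid
#'
#' Voxel field over the analysis volume. Each voxel records in how many frames
#' a real probe heavy site lay within the capture radius of the voxel centre;
#' the average occupancy is counts/nFrames, in [0, 1].
#'
#' @slot origin Numeric length-3 position of the first voxel centre.
#' @slot spacing Voxel spacing (angstrom).
#' @slot dims Integer length-3 voxel counts per axis.
#' @slot counts 3-d integer array of per-voxel frame counts.
#' @slot nFrames Number of frames accumulated.
#' @slot radius Capture radius used (angstrom).
#' @export
setClass("OccupancyGrid",
  representation(
    origin = "numeric", spacing = "numeric", dims = "integer",
    counts = "array", nFrames = "integer", radius = "numeric"
  )
)

setValidity("OccupancyGrid", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (!identical(dim(object@counts), as.integer(object@dims))) {
    return("counts array must match dims")
  }
  if (object@nFrames < 0L) return("nFrames must be >= 0")
  if (object@nFrames > 0L &&
      (min(object@counts) < 0L || max(object@counts) > object@nFrames)) {
    return("per-voxel counts must lie in [0, nFrames]")
  }
  TRUE
})

#' Titration fit result
#'
#' Aggregated result of a B-value titration: the per-repeat logistic fits on
#' the Adams-value scale, the derived dissociation constant and standard
#' binding free energy with standard errors, and the Kendall tau concordance
#' of occupancy with B across all repeats.
#'
#' @slot b50 Mean fitted B50 across repeats.
#' @slot b50Se Standard error of the mean B50.
#' @slot k Mean logistic steepness.
#' @slot kd Mean dissociation constant (mol/L).
#' @slot kdSe Standard error of the mean K_D.
#' @slot dg Standard binding free energy (kcal/mol).
#' @slot dgSe Standard error on dg.
#' @slot kendallTau Kendall tau of occupancy vs B over all rows.
#' @slot perRepeat data.frame of per-repeat fits (repeat, b50, k, kd).
#' @export
setClass("TitrationFit",
  representation(
    b50 = "numeric", b50Se = "numeric", k = "numeric", kd = "numeric",
    kdSe = "numeric", dg = "numeric", dgSe = "numeric",
    kendallTau = "numeric", perRepeat = "data.frame"
  )
)

setValidity("TitrationFit", function(object) {
  if (length(object@kd) && is.finite(object@kd) && object@kd <= 0) {
    return("kd must be > 0")
  }
  TRUE
})

#' Binding-mode populations
#'
#' Per-frame mode labels with counts and fractions, from dihedral binning or
#' pairwise-RMSD clustering. Fractions sum to 1 over assigned frames.
#'
#' @slot labels Integer mode label per assigned frame.
#' @slot counts Named integer vector of frames per mode.
#' @slot fractions Named numeric vector of populations per mode.
#' @slot nSkipped Frames skipped (molecule absent).
#' @slot method "dihedral" or "rmsd".
#' @slot projection Optional nFrames x 2 matrix of projection coordinates.
#' @export
setClass("ModePopulations",
  representation(
    labels = "integer", counts = "integer", fractions = "numeric",
    nSkipped = "integer", method = "character",
    projection = "matrixOrNULL"
  ),
  prototype(nSkipped = 0L, projection = NULL)
)

setValidity("ModePopulations", function(object) {
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-8) {
    return("fractions must sum to 1")
  }
  TRUE
})
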