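#' @describeIn ToySystem-class Compact summary of box, species and wells.
#' @param object Object to display.
#' @export
setMethod("show", "ToySystem", function(object) {
  cat("ToySystem:", paste(sprintf("%.1f", object@box@edge), collapse = " x "),
      "A box,", length(object@species), "species,",
      length(object@wells), "well(s),",
      sprintf("T = %g K, cutoff = %g A\n", object@temperature,
              object@cutoff))
  for (nm in names(object@species)) {
    sp <- object@species[[nm]]
    cat(sprintf("  %s: %d site(s), eps = %g, sigma = %g\n", nm,
                nrow(sp@siteCoords), sp@epsilon[1], sp@sigma[1]))
  }
  invisible(NULL)
})

#' @describeIn SystemState-class Molecule and ghost counts.
#' @param object Object to display.
#' @export
setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d molecule(s) (%d real, %d ghost), %d site(s)\n",
              nrow(object@molecules), sum(!object@ghost), sum(object@ghost),
              nrow(object@positions)))
  invisible(NULL)
})

#' @describeIn NCMCProtocol-class Protocol summary with switching time.
#' @param object Object to display.
#' @export
setMethod("show", "NCMCProtocol", function(object) {
  cat(sprintf(
    "NCMCProtocol: nPert = %d, nProp = %d, dt = %g fs (tau = %g ps), %s\n",
    object@nPert, object@nProp, object@dtFs, switchingTime(object),
    object@direction
  ))
  invisible(NULL)
})

#' @describeIn AdamsSpec-class Conversion-ready parameter summary.
#' @param object Object to display.
#' @export
setMethod("show", "AdamsSpec", function(object) {
  cat(sprintf(
    "AdamsSpec: mu' = %g +/- %g kcal/mol, T = %g K, V_GCMC = %g A^3\n",
    object@muEx, object@muExSe, object@temperature, object@vGCMC
  ))
  invisible(NULL)
})

#' @describeIn TitrationFit-class Fitted affinity summary.
#' @param object Object to display.
#' @export
setMethod("show", "TitrationFit", function(object) {
  cat(sprintf(
    "TitrationFit: B50 = %.3f +/- %.3f, K_D = %.4g +/- %.2g M\n",
    object@b50, object@b50Se, object@kd, object@kdSe
  ))
  cat(sprintf("  dG = %.3f +/- %.3f kcal/mol, Kendall tau = %.3f (%d repeats)\n",
              object@dg, object@dgSe, object@kendallTau,
              nrow(object@perRepeat)))
  invisible(NULL)
})

#' @describeIn OccupancyGrid-class Grid geometry and occupancy range.
#' @param object Object to display.
#' @export
setMethod("show", "OccupancyGrid", function(object) {
  o <- gridOccupancy(object)
  cat(sprintf(
    "OccupancyGrid: %d x %d x %d voxels at %g A, %d frame(s), max <O> = %.3f\n",
    object@dims[1], object@dims[2], object@dims[3], object@spacing,
    object@nFrames, if (length(o)) max(o) else 0
  ))
  invisible(NULL)
})

#' @describeIn ModePopulations-class Mode fractions.
#' @param object Object to display.
#' @export
setMethod("show", "ModePopulations", function(object) {
  cat(sprintf("ModePopulations (%s): %s; %d frame(s) skipped\n",
              object@method,
              paste(sprintf("%s = %.3f", names(object@fractions),
                            object@fractions), collapse = ", "),
              object@nSkipped))
  invisible(NULL)
})
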