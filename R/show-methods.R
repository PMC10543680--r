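#' @describeIn SLDLevelProfile-class concise display
#' @param object object to display
#' @export
setMethod("show", "SLDLevelProfile", function(object) {
  n <- length(object@thickness)
  cat(sprintf("SLDLevelProfile: %d level(s), total thickness %.2f A\n",
              n, sum(object@thickness)))
  if (n > 0)
    cat(sprintf("  z in [%.2f, %.2f] A, solvent SLD %.3e 1/A^2\n",
                object@zBase, object@zBase + sum(object@thickness),
                object@sldSolvent))
})

#' @describeIn Island-class concise display
#' @param object object to display
#' @export
setMethod("show", "Island", function(object) {
  cat(sprintf("Island: %d shell(s), radii %s A\n", length(object@radii),
              paste(format(object@radii, digits = 4), collapse = ", ")))
})

#' @describeIn MembraneSystem-class concise display
#' @param object object to display
#' @export
setMethod("show", "MembraneSystem", function(object) {
  cat(sprintf("MembraneSystem (%s probe)\n", object@probe@probe))
  cat(sprintf("  bilayer: %d levels, thickness %.2f A\n",
              length(object@bilayer@thickness),
              totalThickness(object@bilayer)))
  if (is.null(object@island)) cat("  no island\n")
  else cat(sprintf("  island: %d shell(s), Rmax %.1f A; lattice a = %.1f A, ga = %.2f\n",
                   length(object@island@radii), max(object@island@radii),
                   object@lattice@a, object@lattice@ga))
  cat(sprintf("  stack: N = %d (%s), c = %.1f A\n", object@stack@N,
              object@stack@theory, object@stack@c))
})

#' @describeIn ScatteringCurve-class concise display
#' @param object object to display
#' @export
setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve '%s' (%s): %d points, q in [%.4g, %.4g] 1/A%s\n",
              object@label, if (nzchar(object@probe)) object@probe else "?",
              length(object@q), min(object@q), max(object@q),
              if (is.null(object@sigma)) ", no uncertainties" else ""))
})

#' Number of levels of a profile
#' @param profile an \code{SLDLevelProfile}
#' @return integer level count
#' @export
nLevels <- function(profile) length(profile@thickness)

#' Maximum island radius
#' @param island an \code{Island}
#' @return outer radius (Angstrom)
#' @export
maxRadius <- function(island) max(island@radii)
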