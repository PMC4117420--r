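#' @title Accessors for hydrofilm objects
#' @name accessors
#' @rdname accessors
#' @param x an object.
NULL

#' @rdname accessors
#' @export
setGeneric("spins", function(x) standardGeneric("spins"))

#' @rdname accessors
#' @export
setMethod("spins", "FilmLattice", function(x) x@spins)

#' @rdname accessors
#' @export
setGeneric("latticeWidth", function(x) standardGeneric("latticeWidth"))

#' @rdname accessors
#' @export
setMethod("latticeWidth", "FilmLattice", function(x) nrow(x@spins))

#' @rdname accessors
#' @export
setGeneric("latticeHeight", function(x) standardGeneric("latticeHeight"))

#' @rdname accessors
#' @export
setMethod("latticeHeight", "FilmLattice", function(x) ncol(x@spins))

#' @rdname accessors
#' @export
setGeneric("nOccupied", function(x) standardGeneric("nOccupied"))

#' @rdname accessors
#' @export
setMethod("nOccupied", "FilmLattice", function(x) sum(x@spins >= 0L))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setMethod("occupancy", "FilmLattice",
          function(x) sum(x@spins >= 0L) / length(x@spins))

#' @rdname accessors
#' @export
setGeneric("tableClasses", function(x) standardGeneric("tableClasses"))

#' @rdname accessors
#' @export
setMethod("tableClasses", "InteractionTable", function(x) x@cls)

#' @rdname accessors
#' @export
setGeneric("p3Enabled", function(x) standardGeneric("p3Enabled"))

#' @rdname accessors
#' @export
setMethod("p3Enabled", "InteractionTable", function(x) x@p3Enabled)

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterLabeling", function(x) x@sizes)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterLabeling", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("clusterWraps", function(x) standardGeneric("clusterWraps"))

#' @rdname accessors
#' @export
setMethod("clusterWraps", "ClusterLabeling", function(x) x@wraps)

#' @rdname accessors
#' @export
setGeneric("growthLabel", function(x) standardGeneric("growthLabel"))

#' @rdname accessors
#' @export
setMethod("growthLabel", "GrowthFit", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("fitWindow", function(x) standardGeneric("fitWindow"))

#' @rdname accessors
#' @export
setMethod("fitWindow", "GrowthFit", function(x) x@window)

setMethod("show", "FilmLattice", function(object) {
  cat(sprintf("FilmLattice: %d x %d sites, %d occupied (%.3f)\n",
              latticeWidth(object), latticeHeight(object),
              nOccupied(object), occupancy(object)))
})

setMethod("show", "InteractionTable", function(object) {
  cls <- object@cls
  cat(sprintf(paste0("InteractionTable: %d trimer, %d P6-dock, %d P3-dock ",
                     "ordered entries (P3 %s)\n"),
              sum(cls == 1L), sum(cls == 2L), sum(cls == 3L),
              if (object@p3Enabled) "enabled" else "disabled"))
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams: J0 = %g, J1 = %g, J2 = %g, Jsurf = %g, pAbsent = %g (kT units)\n",
              object@J0, object@J1, object@J2, object@Jsurf, object@pAbsent))
})

setMethod("show", "ClusterLabeling", function(object) {
  cat(sprintf("ClusterLabeling: %d clusters, largest = %d, percolated = %s\n",
              length(object@sizes),
              if (length(object@sizes)) max(object@sizes) else 0L,
              any(object@wraps)))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit: label = %s (window %g..%g, %d points)\n",
              object@label, object@window[1], object@window[2],
              object@nPoints))
  cat(sprintf("  linear: size = %.3g + %.3g * t  (AICc %.2f)\n",
              object@linearFit[1], object@linearFit[2], object@linearAICc))
  cat(sprintf("  exponential: size = %.3g * exp(%.3g * t)  (AICc %.2f)\n",
              exp(object@expFit[1]), object@expFit[2], object@expAICc))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "FilmScenario", function(object) {
  cat(sprintf("FilmScenario '%s': %d x %d cells (%d x %d sites), %d sweeps, %d seed(s)\n",
              object@name, object@cells, object@cells,
              14L * object@cells, 14L * object@cells,
              object@sweeps, length(object@seeds)))
})

setMethod("show", "P6Params", function(object) {
  cat(sprintf("P6Params: r = %.3f A, d = %.3f A, psi = %.4f rad, euler = (%.4f, %g, %g)\n",
              object@rTrimer, object@dTrimers, object@psi,
              object@euler[1], object@euler[2], object@euler[3]))
})
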