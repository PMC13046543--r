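#' @include AllClasses.R
NULL

#' Accessors for dynetfnc classes
#'
#' Small accessor generics for the package's S4 containers. Prefer these over
#' direct slot access.
#'
#' @param object an object of the documented class.
#' @return The slot contents (matrix, list, numeric or integer as documented
#'   for each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setMethod("boldData", "BoldSeries", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setMethod("trSeconds", "BoldSeries", function(object) object@trSeconds)

#' @rdname accessors
#' @export
setGeneric("maskIndices", function(object) standardGeneric("maskIndices"))
#' @rdname accessors
#' @export
setMethod("maskIndices", "BoldSeries", function(object) object@maskIndices)
#' @rdname accessors
#' @export
setMethod("maskIndices", "GroundTruth", function(object) object@maskIndices)

#' @rdname accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setMethod("gridShape", "BoldSeries", function(object) object@gridShape)
#' @rdname accessors
#' @export
setMethod("gridShape", "GroundTruth", function(object) object@gridShape)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "BoldSeries", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("spatialMaps", function(object) standardGeneric("spatialMaps"))
#' @rdname accessors
#' @export
setMethod("spatialMaps", "ComponentSet", function(object) object@spatialMaps)
#' @rdname accessors
#' @export
setMethod("spatialMaps", "GroundTruth", function(object) object@spatialSources)

#' @rdname accessors
#' @export
setGeneric("timeCourses", function(object) standardGeneric("timeCourses"))
#' @rdname accessors
#' @export
setMethod("timeCourses", "ComponentSet", function(object) object@timeCourses)
#' @rdname accessors
#' @export
setMethod("timeCourses", "GroundTruth", function(object) object@timeCourses)

#' @rdname accessors
#' @export
setGeneric("stabilityIq", function(object) standardGeneric("stabilityIq"))
#' @rdname accessors
#' @export
setMethod("stabilityIq", "ComponentSet", function(object) object@stabilityIq)

#' @rdname accessors
#' @export
setGeneric("componentLabels", function(object) standardGeneric("componentLabels"))
#' @rdname accessors
#' @export
setMethod("componentLabels", "ComponentSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("templateCorrelations",
           function(object) standardGeneric("templateCorrelations"))
#' @rdname accessors
#' @export
setMethod("templateCorrelations", "ComponentSet",
          function(object) object@templateCorrelations)

#' @rdname accessors
#' @export
setGeneric("fncMatrices", function(object) standardGeneric("fncMatrices"))
#' @rdname accessors
#' @export
setMethod("fncMatrices", "WindowedFNC", function(object) object@matrices)

#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setMethod("nWindows", "WindowedFNC", function(object) dim(object@matrices)[1])
#' @rdname accessors
#' @export
setMethod("nWindows", "WindowSegmentation", function(object) object@nWindows)

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setMethod("windowStarts", "WindowedFNC",
          function(object) object@windowStartIndices)
#' @rdname accessors
#' @export
setMethod("windowStarts", "WindowSegmentation",
          function(object) object@startIndices)

#' @rdname accessors
#' @export
setGeneric("stateK", function(object) standardGeneric("stateK"))
#' @rdname accessors
#' @export
setMethod("stateK", "StateModel", function(object) object@k)

#' @rdname accessors
#' @export
setGeneric("stateCentroids", function(object) standardGeneric("stateCentroids"))
#' @rdname accessors
#' @export
setMethod("stateCentroids", "StateModel", function(object) object@centroids)

#' @rdname accessors
#' @export
setGeneric("stateAssignments", function(object) standardGeneric("stateAssignments"))
#' @rdname accessors
#' @export
setMethod("stateAssignments", "StateModel", function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("validityCurve", function(object) standardGeneric("validityCurve"))
#' @rdname accessors
#' @export
setMethod("validityCurve", "StateModel", function(object) object@validityCurve)

#' @rdname accessors
#' @export
setGeneric("scvSources", function(object) standardGeneric("scvSources"))
#' @rdname accessors
#' @export
setMethod("scvSources", "SCVSet", function(object) object@sources)

#' @rdname accessors
#' @export
setGeneric("scvDemixing", function(object) standardGeneric("scvDemixing"))
#' @rdname accessors
#' @export
setMethod("scvDemixing", "SCVSet", function(object) object@demixing)

#' @rdname accessors
#' @export
setGeneric("datasetIndex", function(object) standardGeneric("datasetIndex"))
#' @rdname accessors
#' @export
setMethod("datasetIndex", "SCVSet", function(object) object@datasetIndex)

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "SCVSet", function(object) object@nComponents)
#' @rdname accessors
#' @export
setMethod("nComponents", "ComponentSet",
          function(object) nrow(object@spatialMaps))

#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(object) standardGeneric("stateCovariances"))
#' @rdname accessors
#' @export
setMethod("stateCovariances", "GroundTruth",
          function(object) object@stateCovariances)

#' @rdname accessors
#' @export
setGeneric("stateSequences", function(object) standardGeneric("stateSequences"))
#' @rdname accessors
#' @export
setMethod("stateSequences", "GroundTruth", function(object) object@stateSequences)

#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))
#' @rdname accessors
#' @export
setMethod("clinicalTable", "GroundTruth", function(object) object@clinicalTable)

#' Extract one SCV as a matrix
#'
#' Stacks the n-th source row from every (subject, window) dataset into one
#' (M*L) x V matrix: the estimated source component vector.
#'
#' @param object an \linkS4class{SCVSet}.
#' @param n component index.
#' @return (M*L) x V numeric matrix, rows in \code{datasetIndex} order.
#' @export
setGeneric("scvMatrix", function(object, n) standardGeneric("scvMatrix"))
#' @rdname scvMatrix
#' @export
setMethod("scvMatrix", "SCVSet", function(object, n) {
  stopifnot(n >= 1L, n <= object@nComponents)
  do.call(rbind, lapply(object@sources, function(s) s[n, , drop = TRUE]))
})

setMethod("show", "BoldSeries", function(object) {
  cat(sprintf("BoldSeries '%s': %d TRs x %d voxels (TR = %g s, grid %s)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@trSeconds, paste(object@gridShape, collapse = "x")))
})

setMethod("show", "ComponentSet", function(object) {
  n <- nrow(object@spatialMaps)
  lab <- object@labels
  cat(sprintf("ComponentSet: %d components x %d voxels; %d subject time-course set(s)\n",
              n, ncol(object@spatialMaps), length(object@timeCourses)))
  if (!all(is.na(object@stabilityIq)))
    cat(sprintf("  ICASSO iq: median %.3f (min %.3f)\n",
                stats::median(object@stabilityIq), min(object@stabilityIq)))
  if (!all(is.na(lab)))
    cat(sprintf("  labels: %d network, %d artifact\n",
                sum(lab != "artifact", na.rm = TRUE),
                sum(lab == "artifact", na.rm = TRUE)))
})

setMethod("show", "WindowedFNC", function(object) {
  d <- dim(object@matrices)
  cat(sprintf("WindowedFNC: %d windows of %d x %d (width %d TRs, step %d)\n",
              d[1], d[2], d[3], object@windowWidthTrs, object@stepTrs))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k = %d states, %d subjects, %d-dim centroids\n",
              object@k, length(object@assignments), ncol(object@centroids)))
})

setMethod("show", "WindowSegmentation", function(object) {
  cat(sprintf("WindowSegmentation '%s': L = %d windows of %d TRs (overlap %.0f%%)\n",
              object@subjectId, object@nWindows, object@windowLengthTrs,
              100 * object@overlapFraction))
})

setMethod("show", "SCVSet", function(object) {
  cat(sprintf("SCVSet: N = %d components over %d (subject, window) datasets\n",
              object@nComponents, length(object@sources)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d sources, %d states, %d subjects (seed %d)\n",
              nrow(object@spatialSources), length(object@stateCovariances),
              length(object@stateSequences), object@seed))
})
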