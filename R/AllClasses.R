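#' @import methods
NULL

#' BoldSeries: one subject's masked BOLD data
#'
#' Container for a single subject's preprocessed resting-state BOLD series in
#' time-by-voxel layout, together with the mask and acquisition metadata needed
#' to map columns back onto the 3-D grid.
#'
#' Column \code{j} of \code{data} is the time series of the voxel whose linear
#' index (column-major, 1-based, a pure function of the mask) is
#' \code{maskIndices[j]}. All entries must be finite.
#'
#' @slot data numeric T x V matrix (arbitrary BOLD units or z-scored).
#' @slot trSeconds repetition time in seconds.
#' @slot maskIndices integer vector of length V: linear indices of in-mask
#'   voxels into the 3-D grid, strictly increasing.
#' @slot gridShape integer vector of length 3: dimensions of the 3-D grid.
#' @slot subjectId character scalar.
#'
#' @export
setClass("BoldSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    maskIndices = "integer",
    gridShape = "integer",
    subjectId = "character"
  )
)

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (nrow(object@data) < 2) msg <- c(msg, "need at least 2 time points (T >= 2)")
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(object@gridShape) != 3L) msg <- c(msg, "gridShape must have length 3")
  if (ncol(object@data) != length(object@maskIndices))
    msg <- c(msg, sprintf("V mismatch: %d data columns vs %d mask voxels",
                          ncol(object@data), length(object@maskIndices)))
  if (is.unsorted(object@maskIndices, strictly = TRUE))
    msg <- c(msg, "maskIndices must be strictly increasing")
  if (length(object@maskIndices) > 0 &&
      (min(object@maskIndices) < 1L ||
       max(object@maskIndices) > prod(object@gridShape)))
    msg <- c(msg, "maskIndices out of grid range")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a BoldSeries
#'
#' @param data numeric T x V matrix.
#' @param trSeconds repetition time in seconds (default 2).
#' @param maskIndices integer vector of in-mask linear voxel indices.
#' @param gridShape integer vector of length 3.
#' @param subjectId subject identifier.
#' @return A \linkS4class{BoldSeries} object.
#' @export
BoldSeries <- function(data, trSeconds = 2, maskIndices, gridShape,
                       subjectId = "subject") {
  new("BoldSeries", data = as.matrix(data), trSeconds = as.numeric(trSeconds),
      maskIndices = as.integer(maskIndices), gridShape = as.integer(gridShape),
      subjectId = as.character(subjectId))
}

#' ComponentSet: spatial maps and time courses from a decomposition
#'
#' Holds the result of a (group or subject-level) ICA decomposition: z-scaled
#' spatial maps, per-subject time courses, ICASSO stability indices, and
#' template-based labels.
#'
#' @slot spatialMaps numeric N x V matrix, each row z-scaled over the mask.
#' @slot timeCourses list of per-subject T x N matrices (may be empty before
#'   back-reconstruction).
#' @slot stabilityIq numeric length-N vector in [0, 1] (NA if ICASSO not run).
#' @slot labels character length-N: network name or "artifact" (NA if not
#'   labeled yet).
#' @slot templateCorrelations data.frame with columns \code{component},
#'   \code{template}, \code{r} (zero rows if not labeled).
#' @export
setClass("ComponentSet",
  representation(
    spatialMaps = "matrix",
    timeCourses = "list",
    stabilityIq = "numeric",
    labels = "character",
    templateCorrelations = "data.frame"
  )
)

setValidity("ComponentSet", function(object) {
  msg <- character()
  n <- nrow(object@spatialMaps)
  if (length(object@stabilityIq) != n) msg <- c(msg, "stabilityIq length != N")
  if (length(object@labels) != n) msg <- c(msg, "labels length != N")
  ok <- is.na(object@stabilityIq) |
    (object@stabilityIq >= -1e-8 & object@stabilityIq <= 1 + 1e-8)
  if (!all(ok)) msg <- c(msg, "stabilityIq values must lie in [0, 1]")
  for (tc in object@timeCourses) {
    if (!is.matrix(tc) || ncol(tc) != n) {
      msg <- c(msg, "each time-course matrix must be T x N")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

ComponentSet <- function(spatialMaps, timeCourses = list(),
                         stabilityIq = rep(NA_real_, nrow(spatialMaps)),
                         labels = rep(NA_character_, nrow(spatialMaps)),
                         templateCorrelations = data.frame(
                           component = integer(), template = character(),
                           r = numeric())) {
  new("ComponentSet", spatialMaps = spatialMaps, timeCourses = timeCourses,
      stabilityIq = stabilityIq, labels = labels,
      templateCorrelations = templateCorrelations)
}

#' WindowedFNC: sliding-window functional network connectivity
#'
#' A stack of symmetric per-window component-correlation matrices.
#'
#' @slot matrices numeric array W x N x N; each slice symmetric with unit
#'   diagonal and entries in [-1, 1].
#' @slot windowWidthTrs window width in TRs.
#' @slot stepTrs step between consecutive window starts in TRs.
#' @slot windowStartIndices integer length-W vector of 0-based start rows.
#' @export
setClass("WindowedFNC",
  representation(
    matrices = "array",
    windowWidthTrs = "integer",
    stepTrs = "integer",
    windowStartIndices = "integer"
  )
)

setValidity("WindowedFNC", function(object) {
  msg <- character()
  d <- dim(object@matrices)
  if (length(d) != 3L || d[2] != d[3]) msg <- c(msg, "matrices must be W x N x N")
  if (length(object@windowStartIndices) != d[1])
    msg <- c(msg, "windowStartIndices length != W")
  if (any(abs(object@matrices) > 1 + 1e-8)) msg <- c(msg, "entries outside [-1, 1]")
  for (w in seq_len(min(d[1], 3L))) {
    m <- object@matrices[w, , ]
    if (max(abs(m - t(m))) > 1e-8) { msg <- c(msg, "matrices not symmetric"); break }
    if (max(abs(diag(m) - 1)) > 1e-8) { msg <- c(msg, "diagonal not 1"); break }
  }
  if (length(msg)) msg else TRUE
})

#' StateModel: k-means connectivity states
#'
#' @slot k number of states.
#' @slot centroids k x E matrix (E = N(N-1)/2 Fisher-z upper-triangle values).
#' @slot assignments list of per-subject integer vectors (length W each),
#'   values in 1..k.
#' @slot validityCurve data.frame with columns \code{k} and \code{score}
#'   (within/between dispersion ratio) used for automatic k selection; zero
#'   rows when k was fixed by the caller.
#' @export
setClass("StateModel",
  representation(
    k = "integer",
    centroids = "matrix",
    assignments = "list",
    validityCurve = "data.frame"
  )
)

setValidity("StateModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k) msg <- c(msg, "centroid count != k")
  for (a in object@assignments) {
    if (any(a < 1L | a > object@k)) { msg <- c(msg, "assignment out of 1..k"); break }
  }
  if (length(msg)) msg else TRUE
})

#' WindowSegmentation: overlapping windows of one subject's series
#'
#' @slot windows list of L matrices, each T_w x V (variance-normalized per
#'   voxel within window when requested).
#' @slot windowLengthTrs window length t in TRs.
#' @slot nWindows number of windows L.
#' @slot overlapFraction fractional overlap between consecutive windows.
#' @slot startIndices integer 0-based start TRs of each window.
#' @slot subjectId subject identifier.
#' @export
setClass("WindowSegmentation",
  representation(
    windows = "list",
    windowLengthTrs = "integer",
    nWindows = "integer",
    overlapFraction = "numeric",
    startIndices = "integer",
    subjectId = "character"
  )
)

setValidity("WindowSegmentation", function(object) {
  msg <- character()
  if (length(object@windows) != object@nWindows)
    msg <- c(msg, "window list length != nWindows")
  if (length(msg)) msg else TRUE
})

#' SCVSet: IVA output organized by source component vector
#'
#' IVA estimates one demixing matrix per (subject, window) dataset. Row n of
#' every dataset's source matrix belongs to source component vector (SCV) n:
#' the collection of the n-th spatially dynamic component (SDC) across all
#' subjects and windows.
#'
#' @slot demixing list over datasets of N x T_w demixing matrices (whitening
#'   included), named "m<subject>_l<window>".
#' @slot sources list over datasets of N x V source-map matrices (same names).
#' @slot datasetIndex data.frame with columns \code{dataset}, \code{subject},
#'   \code{window} giving the (m, l) identity of each list element.
#' @slot nComponents number of components N.
#' @slot converged logical flags for the IVA-G and IVA-L stages.
#' @export
setClass("SCVSet",
  representation(
    demixing = "list",
    sources = "list",
    datasetIndex = "data.frame",
    nComponents = "integer",
    converged = "logical"
  )
)

setValidity("SCVSet", function(object) {
  msg <- character()
  if (length(object@demixing) != length(object@sources))
    msg <- c(msg, "demixing/sources length mismatch")
  if (nrow(object@datasetIndex) != length(object@sources))
    msg <- c(msg, "datasetIndex rows != number of datasets")
  for (s in object@sources) {
    if (nrow(s) != object@nComponents) {
      msg <- c(msg, "each source matrix must have N rows"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot spatialSources N x V z-scaled source maps.
#' @slot maskIndices linear indices of in-mask voxels.
#' @slot gridShape 3-int grid dimensions.
#' @slot stateCovariances list of K base N x N state covariance matrices
#'   (symmetric positive definite, unit diagonal).
#' @slot subjectCovariances list over subjects of lists of K covariance
#'   matrices actually used (after group/clinical effects).
#' @slot stateSequences list over subjects of length-T state label vectors.
#' @slot timeCourses list over subjects of T x N source time courses.
#' @slot jitterFields list over subjects of lists over windows of N x V
#'   multiplicative modulation fields (empty when jitter is 0).
#' @slot clinicalTable data.frame: subject_id, group, score, duration_months.
#' @slot plantedEffects the effect specification used.
#' @slot genParams list of generation parameters (T, snr, jitter, window
#'   geometry, ...) recorded for reproducibility.
#' @slot seed integer seed.
#' @export
setClass("GroundTruth",
  representation(
    spatialSources = "matrix",
    maskIndices = "integer",
    gridShape = "integer",
    stateCovariances = "list",
    subjectCovariances = "list",
    stateSequences = "list",
    timeCourses = "list",
    jitterFields = "list",
    clinicalTable = "data.frame",
    plantedEffects = "list",
    genParams = "list",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  for (C in object@stateCovariances) {
    if (max(abs(C - t(C))) > 1e-10) { msg <- c(msg, "state covariance not symmetric"); break }
    if (max(abs(diag(C) - 1)) > 1e-8) { msg <- c(msg, "state covariance diagonal != 1"); break }
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) { msg <- c(msg, "state covariance not positive definite"); break }
  }
  K <- length(object@stateCovariances)
  for (s in object@stateSequences) {
    if (!all(seq_len(K) %in% s)) {
      msg <- c(msg, "a state sequence does not visit every state"); break
    }
  }
  if (length(msg)) msg else TRUE
})
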