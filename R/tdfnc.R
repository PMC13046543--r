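# Temporal dynamic functional network connectivity.
#
# Static FNC is the Pearson correlation of component time courses over the
# whole series; dynamic FNC slides a rectangular window (width 18 TRs, step 1
# by default) along the series. Windows are summarized by the Fisher-z
# transformed upper triangle, reduced to high-variance exemplars, and
# clustered by two-stage k-means into recurring connectivity states.

#' Static functional network connectivity
#'
#' Pearson correlation matrix of component time courses over the entire
#' series.
#'
#' @param timeCourses T x N numeric matrix (T >= 3).
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
staticFNC <- function(timeCourses) {
  timeCourses <- as.matrix(timeCourses)
  stopifnot(nrow(timeCourses) >= 3L)
  sds <- apply(timeCourses, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant time course for component(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  stats::cor(timeCourses)
}

#' Sliding-window dynamic FNC
#'
#' Window w (0-based) covers rows \code{[w*step, w*step + width)}; the Pearson
#' correlation matrix is computed per window. The number of windows is
#' \code{W = floor((T - width)/step) + 1}.
#'
#' @param timeCourses T x N numeric matrix.
#' @param widthTrs window width in TRs (<= T; paper-scale default 18).
#' @param stepTrs step between window starts in TRs (>= 1; default 1).
#' @return A \linkS4class{WindowedFNC}.
#' @export
slidingWindowFNC <- function(timeCourses, widthTrs = 18L, stepTrs = 1L) {
  timeCourses <- as.matrix(timeCourses)
  Tlen <- nrow(timeCourses)
  N <- ncol(timeCourses)
  widthTrs <- as.integer(widthTrs)
  stepTrs <- as.integer(stepTrs)
  if (widthTrs > Tlen)
    stop(sprintf("window width %d exceeds series length %d", widthTrs, Tlen))
  stopifnot(stepTrs >= 1L, widthTrs >= 3L)
  W <- (Tlen - widthTrs) %/% stepTrs + 1L
  starts <- (seq_len(W) - 1L) * stepTrs
  mats <- array(0, c(W, N, N))
  for (w in seq_len(W)) {
    seg <- timeCourses[(starts[w] + 1L):(starts[w] + widthTrs), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("constant time course in window %d for component(s): %s",
                   w, paste(which(sds == 0), collapse = ", ")))
    mats[w, , ] <- stats::cor(seg)
  }
  new("WindowedFNC", matrices = mats, windowWidthTrs = widthTrs,
      stepTrs = stepTrs, windowStartIndices = as.integer(starts))
}

#' Select exemplar windows by local FC variance
#'
#' Computes, per window, the variance across the E = N(N-1)/2 upper-triangle
#' correlations and returns the indices that are strict local maxima of this
#' variance sequence (an endpoint qualifies when it exceeds its single
#' neighbor). If no strict local maximum exists (e.g. a constant sequence),
#' the first global maximum is returned as fallback.
#'
#' @param wfnc a \linkS4class{WindowedFNC} with at least 3 windows.
#' @return integer vector of exemplar window indices (1-based), always
#'   non-empty.
#' @export
selectExemplars <- function(wfnc) {
  mats <- wfnc@matrices
  W <- dim(mats)[1]
  stopifnot(W >= 3L)
  v <- vapply(seq_len(W), function(w) stats::var(upperTriVec(mats[w, , ])),
              numeric(1))
  isMax <- logical(W)
  isMax[1] <- v[1] > v[2]
  isMax[W] <- v[W] > v[W - 1]
  if (W > 2L) {
    mid <- 2:(W - 1L)
    isMax[mid] <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  }
  idx <- which(isMax)
  if (length(idx) == 0L) idx <- which.max(v)  # first index on ties
  idx
}

# Fisher-z upper-triangle vectors of all windows of one WindowedFNC: W x E.
windowVectors <- function(wfnc) {
  mats <- wfnc@matrices
  W <- dim(mats)[1]
  t(vapply(seq_len(W), function(w) fisherZ(upperTriVec(mats[w, , ])),
           numeric(dim(mats)[2] * (dim(mats)[2] - 1) / 2)))
}

# One two-stage k-means fit at fixed k on (exemplars, all windows).
# Stage 1: best of nInit k-means++ seeded Lloyd runs on the exemplar vectors;
# stage 2: Lloyd refinement over all windows from the stage-1 centroids.
fitStates <- function(exemplarVecs, allVecs, k, nInit = 10L) {
  if (nrow(unique(exemplarVecs)) < k)
    stop(sprintf("fewer than k = %d distinct exemplar vectors", k))
  best <- NULL
  for (i in seq_len(nInit)) {
    ctr <- kmeansPPInit(exemplarVecs, k)
    km <- suppressWarnings(stats::kmeans(exemplarVecs, centers = ctr,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  km2 <- suppressWarnings(stats::kmeans(allVecs, centers = best$centers,
                                        iter.max = 100L, algorithm = "Lloyd"))
  km2
}

# Within/between dispersion ratio used as the validity score for k selection.
validityScore <- function(km) {
  within <- sqrt(km$tot.withinss / length(km$cluster))
  d <- stats::dist(km$centers)
  between <- mean(d)
  within / between
}

#' Cluster windowed FNC into connectivity states
#'
#' Two-stage k-means over all subjects' windows: high-variance exemplar
#' windows (from [selectExemplars()]) are clustered first (best of 10
#' k-means++ seeded Lloyd runs), and the resulting centroids initialize a
#' Lloyd refinement over every window of every subject. Correlations are
#' Fisher-z transformed before clustering. With \code{k = "auto"} the fit is
#' evaluated for k = 2..10 by the within/between dispersion ratio and the
#' elbow of that curve (the point farthest below the chord joining its ends)
#' is selected. Deterministic given \code{seed}.
#'
#' @param wfncList list of per-subject \linkS4class{WindowedFNC} objects
#'   (same N everywhere).
#' @param k number of states, or "auto".
#' @param seed integer seed.
#' @param kRange candidate k values for automatic selection (default 2:10).
#' @return A \linkS4class{StateModel}; \code{assignments} follows the order of
#'   \code{wfncList}, and \code{validityCurve} is filled when k = "auto".
#' @export
clusterStates <- function(wfncList, k = "auto", seed = 1, kRange = 2:10) {
  stopifnot(length(wfncList) >= 1L)
  vecsBySubject <- lapply(wfncList, windowVectors)
  allVecs <- do.call(rbind, vecsBySubject)
  exemplarVecs <- do.call(rbind, lapply(seq_along(wfncList), function(m) {
    vecsBySubject[[m]][selectExemplars(wfncList[[m]]), , drop = FALSE]
  }))
  curve <- data.frame(k = integer(), score = numeric())
  withSeed(seed, {
    if (identical(k, "auto")) {
      kRange <- kRange[kRange <= nrow(unique(exemplarVecs))]
      if (length(kRange) < 2L) stop("too few distinct exemplars for automatic k")
      fits <- lapply(kRange, function(kk) fitStates(exemplarVecs, allVecs, kk))
      score <- vapply(fits, validityScore, numeric(1))
      curve <- data.frame(k = kRange, score = score)
      # elbow: farthest below the chord joining the curve's endpoints
      x <- (kRange - min(kRange)) / diff(range(kRange))
      y <- (score - score[length(score)]) /
        max(abs(score[1] - score[length(score)]), 1e-12)
      chord <- y[1] + (y[length(y)] - y[1]) * x
      kSel <- which.max(chord - y)
      km <- fits[[kSel]]
      k <- kRange[kSel]
    } else {
      k <- as.integer(k)
      km <- fitStates(exemplarVecs, allVecs, k)
    }
    counts <- vapply(vecsBySubject, nrow, integer(1))
    splits <- rep(seq_along(counts), counts)
    new("StateModel", k = k, centroids = unname(km$centers),
        assignments = unname(split(as.integer(km$cluster), splits)),
        validityCurve = curve)
  })
}

#' Per-subject state occupancy metrics
#'
#' For every subject and state: the number of windows assigned to the state,
#' a membership flag (subjects with fewer than \code{minWindows} windows of a
#' state are deemed not to belong to it), and the mean dwell time (average
#' length of consecutive runs, in windows; multiply by the window step for
#' TRs).
#'
#' @param assignments a \linkS4class{StateModel}, or a list of per-subject
#'   integer state vectors.
#' @param minWindows membership threshold (default 10).
#' @param subjectIds optional subject identifiers.
#' @return data.frame: subject_id, state, n_windows, member, mean_dwell.
#' @export
stateMetrics <- function(assignments, minWindows = 10L, subjectIds = NULL) {
  if (methods::is(assignments, "StateModel")) {
    k <- assignments@k
    assignments <- assignments@assignments
  } else {
    stopifnot(length(assignments) >= 1L)
    k <- max(unlist(assignments))
  }
  if (is.null(subjectIds)) subjectIds <- sprintf("sub%02d", seq_along(assignments))
  out <- do.call(rbind, lapply(seq_along(assignments), function(m) {
    a <- assignments[[m]]
    r <- rle(a)
    do.call(rbind, lapply(seq_len(k), function(st) {
      runs <- r$lengths[r$values == st]
      data.frame(subject_id = subjectIds[m], state = st,
                 n_windows = sum(runs),
                 member = sum(runs) >= minWindows,
                 mean_dwell = if (length(runs)) mean(runs) else 0)
    }))
  }))
  rownames(out) <- NULL
  out
}
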