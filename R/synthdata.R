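# Synthetic multi-subject fMRI generator with planted ground truth.
#
# The generator emulates the study design the pipeline is meant for:
# M subjects (half patients "TS", half controls "N"), T = 192 TRs at TR = 2 s,
# a small set of shared spatial sources, a K-state switching inter-source
# covariance, per-window spatial modulation of the maps (the signal IVA models
# and group ICA averages over), i.i.d. Gaussian voxel noise at a requested SNR,
# and a clinical table with optionally planted group/correlation effects.

#' Generate well-separated spatial source maps
#'
#' Places \code{nSources} Gaussian blobs inside an ellipsoidal "brain" mask
#' inscribed in the grid, using greedy farthest-point placement from a seeded
#' random start, then z-scales each map over the mask and applies a few soft
#' decorrelation sweeps so that all pairwise absolute correlations fall below
#' 0.2 (the artifact-screen threshold downstream). Decorrelation leaves the
#' maps blob-like (correlation with the raw bump > 0.95) but adds the shallow
#' negative surround typical of ICA maps.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param nSources number of sources (>= 2).
#' @param blobRadiusVox Gaussian bump radius (SD) in voxels.
#' @param seed integer seed; output is bit-identical for equal arguments.
#' @return list with \code{sources} (N x V z-scaled matrix), \code{maskIndices}
#'   (linear indices of the in-mask voxels, ascending), \code{gridShape},
#'   \code{centers} (N x 3 blob centers).
#' @export
generateSpatialSources <- function(gridShape, nSources, blobRadiusVox = 2,
                                   seed = 1) {
  stopifnot(length(gridShape) == 3L, nSources >= 2L, blobRadiusVox > 0)
  gridShape <- as.integer(gridShape)
  coords <- as.matrix(expand.grid(x = seq_len(gridShape[1]),
                                  y = seq_len(gridShape[2]),
                                  z = seq_len(gridShape[3])))
  ctr <- (gridShape + 1) / 2
  semi <- gridShape / 2 - 0.5
  if (any(semi <= 0)) stop("grid too small to hold an ellipsoidal mask")
  ellDist <- function(pts, axes)
    rowSums((sweep(pts, 2L, ctr) / matrix(axes, nrow(pts), 3L, byrow = TRUE))^2)
  inMask <- ellDist(coords, semi) <= 1
  maskIdx <- which(inMask)              # ascending linear (column-major) order
  maskCoords <- coords[inMask, , drop = FALSE]
  innerAxes <- pmax(semi - blobRadiusVox / 2, 0.5)
  inner <- maskCoords[ellDist(maskCoords, innerAxes) <= 1, , drop = FALSE]
  if (nrow(inner) < nSources)
    stop(sprintf("placement failure: %d candidate centers for %d sources; grid too small",
                 nrow(inner), nSources))
  withSeed(seed, {
    centers <- inner[sample.int(nrow(inner), 1L), , drop = FALSE]
    while (nrow(centers) < nSources) {
      d2 <- vapply(seq_len(nrow(inner)), function(i) {
        min(rowSums(sweep(centers, 2L, inner[i, ])^2))
      }, numeric(1))
      best <- which(d2 == max(d2))
      pick <- best[if (length(best) > 1L) sample.int(length(best), 1L) else 1L]
      centers <- rbind(centers, inner[pick, , drop = FALSE])
    }
    sep <- as.matrix(stats::dist(centers))
    minSep <- min(sep[upper.tri(sep)])
    if (minSep < 2 * blobRadiusVox)
      stop(sprintf("placement failure: achievable center separation %.2f voxels < %g (2 x blob radius); grid too small for %d sources",
                   minSep, 2 * blobRadiusVox, nSources))
    S <- t(apply(centers, 1L, function(cc) {
      exp(-rowSums(sweep(maskCoords, 2L, cc)^2) / (2 * blobRadiusVox^2))
    }))
    S <- zScaleRows(S)
    # soft decorrelation sweeps: subtract each map's projection on the others
    for (it in seq_len(100L)) {
      R <- stats::cor(t(S)); diag(R) <- 0
      if (max(abs(R)) < 0.15) break
      S <- zScaleRows(S - 0.5 * R %*% S)
    }
    R <- stats::cor(t(S)); diag(R) <- 0
    if (max(abs(R)) >= 0.2)
      stop("placement failure: could not decorrelate sources below |r| = 0.2")
    dimnames(S) <- NULL
    list(sources = S, maskIndices = maskIdx, gridShape = gridShape,
         centers = unname(as.matrix(centers)))
  })
}

#' Generate state-switching source time courses
#'
#' Draws a Markov dwell process (geometric segment lengths with the given mean)
#' over K states and, within each segment, zero-mean Gaussian rows with that
#' state's covariance. The first K segments visit every state once in seeded
#' random order (segment lengths capped so all states fit into T), after which
#' the chain moves uniformly among the other states.
#'
#' @param nTimepoints series length T in TRs (>= 2 x dwellMeanTrs).
#' @param stateCovariances list of K symmetric positive-definite N x N
#'   matrices with unit diagonal.
#' @param dwellMeanTrs mean segment length in TRs.
#' @param seed integer seed.
#' @return list with \code{timeCourses} (T x N) and \code{stateSequence}
#'   (length-T integers in 1..K).
#' @export
generateStateTimecourses <- function(nTimepoints, stateCovariances,
                                     dwellMeanTrs = 50, seed = 1) {
  T <- as.integer(nTimepoints)
  K <- length(stateCovariances)
  stopifnot(K >= 1L, dwellMeanTrs >= 1)
  if (T < 2 * dwellMeanTrs && dwellMeanTrs < T)
    stop("nTimepoints must be at least twice the mean dwell time")
  N <- nrow(stateCovariances[[1]])
  chol_k <- lapply(stateCovariances, function(C) {
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10)))
      stop("state covariance is not symmetric")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("state covariance is not positive definite")
    chol(C)
  })
  withSeed(seed, {
    stateSeq <- integer(0)
    coverOrder <- sample.int(K)
    i <- 0L
    prev <- 0L
    while (length(stateSeq) < T) {
      i <- i + 1L
      if (i <= K) {
        st <- coverOrder[i]
      } else {
        cand <- if (K == 1L) 1L else setdiff(seq_len(K), prev)
        st <- cand[if (length(cand) > 1L) sample.int(length(cand), 1L) else 1L]
      }
      len <- 1L + stats::rgeom(1L, prob = min(1, 1 / dwellMeanTrs))
      if (i < K) {
        # keep room so the remaining unvisited states all appear
        maxLen <- T - length(stateSeq) - (K - i)
        len <- max(1L, min(len, maxLen))
      }
      len <- min(len, T - length(stateSeq))
      stateSeq <- c(stateSeq, rep.int(st, len))
      prev <- st
    }
    tc <- matrix(0, T, N)
    pos <- 1L
    r <- rle(stateSeq)
    for (seg in seq_along(r$lengths)) {
      len <- r$lengths[seg]
      st <- r$values[seg]
      tc[pos:(pos + len - 1L), ] <-
        matrix(stats::rnorm(len * N), len, N) %*% chol_k[[st]]
      pos <- pos + len
    }
    list(timeCourses = tc, stateSequence = stateSeq)
  })
}

# Default K state covariance patterns: edges are assigned cyclically to states,
# a state's own edges get `strong`, all others `weak`; repaired to the nearest
# SPD correlation matrix if needed.
defaultStateCovariances <- function(nSources, kStates, strong = 0.65,
                                    weak = 0) {
  ep <- edgePairs(nSources)
  E <- nrow(ep)
  lapply(seq_len(kStates), function(k) {
    v <- rep(weak, E)
    v[seq_len(E) %% kStates == (k %% kStates)] <- strong
    makeSPDCorr(vecToSym(v, nSources, diagVal = 1))
  })
}

# Repair a symmetric matrix to an SPD correlation matrix (eigenvalue floor +
# diagonal rescale). Identity on matrices that are already SPD with unit diag.
makeSPDCorr <- function(C, floorEv = 1e-3) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < floorEv) {
    C <- e$vectors %*% diag(pmax(e$values, floorEv)) %*% t(e$vectors)
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  (C + t(C)) / 2
}

validateEffects <- function(plantedEffects, nSources, kStates) {
  for (nm in names(plantedEffects)) {
    ef <- plantedEffects[[nm]]
    if (!is.null(ef$edge)) {
      if (any(ef$edge < 1L) || any(ef$edge > nSources))
        stop(sprintf("planted effect '%s' references source index outside 1..%d",
                     nm, nSources))
      if (length(ef$edge) != 2L || ef$edge[1] == ef$edge[2])
        stop(sprintf("planted effect '%s' edge must be two distinct indices", nm))
    }
    if (!is.null(ef$state) && (ef$state < 1L || ef$state > kStates))
      stop(sprintf("planted effect '%s' references state outside 1..%d", nm, kStates))
  }
  invisible(TRUE)
}

# Smooth random scalar field over mask coordinates: seeded random quadratic
# polynomial of the (centered, scaled) voxel coordinates, standardized.
smoothField <- function(maskCoords, gridShape) {
  x <- sweep(maskCoords, 2L, gridShape / 2) /
    matrix(gridShape / 2, nrow(maskCoords), 3L, byrow = TRUE)
  basis <- cbind(x, x^2, x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3])
  f <- basis %*% stats::rnorm(ncol(basis))
  as.numeric(scale(f))
}

#' Generate a complete synthetic multi-subject dataset
#'
#' Builds \code{nSubjects} BOLD series as
#' \code{data = timecourses \%*\% (modulated sources) + noise}: shared z-scaled
#' blob sources, per-subject Markov state-switching time courses, per-block
#' smooth multiplicative spatial modulation (strength \code{spatialJitter};
#' blocks are the disjoint step-length segments from which the 50\%-overlap IVA
#' windows are composed), and i.i.d. Gaussian voxel noise scaled so the
#' signal/noise variance ratio equals \code{snr} (\code{snr = Inf} disables
#' noise). The first half of subjects form group "TS", the second half "N".
#'
#' Planted effects (\code{plantedEffects}):
#' \describe{
#'   \item{groupDeltaR}{\code{list(state=, edge=c(i,j), delta=)}: the TS
#'     group's covariance for that state gets \code{delta} added on that edge.}
#'   \item{clinicalR}{\code{list(edge=c(i,j), r=, state=NULL, sd=0.12)}: each
#'     subject's covariance on that edge is perturbed by a random amount (in
#'     the given state, or all states when \code{state} is NULL) and the
#'     clinical score is constructed to correlate with the realized edge value
#'     at level \code{r}.}
#' }
#'
#' The clinical table mirrors the target study: a severity score with mean
#' 44.66 and SD 17.96 clipped to [10, 79], and disease duration of 1-12 months
#' for the TS group (0 for controls).
#'
#' @param nSubjects even number of subjects (half per group).
#' @param nTimepoints series length T in TRs.
#' @param gridShape integer length-3 grid dimensions.
#' @param nSources number of spatial sources N.
#' @param kStates number of connectivity states K.
#' @param snr signal/noise variance ratio (> 0; Inf for noiseless).
#' @param spatialJitter multiplicative modulation SD (0 disables).
#' @param dwellMeanTrs mean state dwell time in TRs.
#' @param plantedEffects list as described above (may be empty).
#' @param stateCovariances optional list of K base covariance matrices;
#'   defaults to well-separated cyclic-edge patterns.
#' @param trSeconds repetition time (seconds).
#' @param ivaWindowTrs,ivaOverlap window geometry the jitter blocks align to.
#' @param blobRadiusVox blob radius passed to [generateSpatialSources()].
#' @param seed integer seed; everything is reproducible from it.
#' @return list with \code{series} (list of \linkS4class{BoldSeries}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
generateDataset <- function(nSubjects = 24, nTimepoints = 192,
                            gridShape = c(16, 16, 16), nSources = 4,
                            kStates = 3, snr = 5, spatialJitter = 0.15,
                            dwellMeanTrs = 50, plantedEffects = list(),
                            stateCovariances = NULL, trSeconds = 2,
                            ivaWindowTrs = 48, ivaOverlap = 0.5,
                            blobRadiusVox = 2, seed = 1) {
  stopifnot(nSubjects %% 2 == 0, snr > 0)
  T <- as.integer(nTimepoints)
  validateEffects(plantedEffects, nSources, kStates)
  if (is.null(stateCovariances))
    stateCovariances <- defaultStateCovariances(nSources, kStates)
  src <- generateSpatialSources(gridShape, nSources, blobRadiusVox,
                                seed = childSeed(seed, 1L))
  S <- src$sources
  V <- ncol(S)
  maskCoords <- as.matrix(expand.grid(x = seq_len(gridShape[1]),
                                      y = seq_len(gridShape[2]),
                                      z = seq_len(gridShape[3])))[src$maskIndices, ,
                                                                  drop = FALSE]
  groups <- rep(c("TS", "N"), each = nSubjects / 2)
  subjectIds <- sprintf("sub%02d", seq_len(nSubjects))

  # per-subject covariances: base + group effect + clinical perturbation
  gd <- plantedEffects$groupDeltaR
  cl <- plantedEffects$clinicalR
  clSd <- if (!is.null(cl$sd)) cl$sd else 0.12
  edgeDev <- withSeed(childSeed(seed, 2L), {
    if (is.null(cl)) rep(0, nSubjects) else stats::rnorm(nSubjects, 0, clSd)
  })
  subjCov <- vector("list", nSubjects)
  realizedEdge <- rep(NA_real_, nSubjects)
  for (m in seq_len(nSubjects)) {
    covs <- stateCovariances
    if (!is.null(gd) && groups[m] == "TS") {
      C <- covs[[gd$state]]
      C[gd$edge[1], gd$edge[2]] <- C[gd$edge[1], gd$edge[2]] + gd$delta
      C[gd$edge[2], gd$edge[1]] <- C[gd$edge[1], gd$edge[2]]
      covs[[gd$state]] <- makeSPDCorr(C)
    }
    if (!is.null(cl)) {
      targetStates <- if (is.null(cl$state)) seq_len(kStates) else cl$state
      for (k in targetStates) {
        C <- covs[[k]]
        v <- min(0.9, max(-0.9, C[cl$edge[1], cl$edge[2]] + edgeDev[m]))
        C[cl$edge[1], cl$edge[2]] <- v
        C[cl$edge[2], cl$edge[1]] <- v
        covs[[k]] <- makeSPDCorr(C)
      }
      kRef <- if (is.null(cl$state)) 1L else cl$state
      realizedEdge[m] <- covs[[kRef]][cl$edge[1], cl$edge[2]]
    }
    subjCov[[m]] <- covs
  }

  # clinical table; score carries the planted correlation when requested
  clin <- withSeed(childSeed(seed, 3L), {
    z <- if (!is.null(cl)) {
      e <- as.numeric(scale(realizedEdge))
      cl$r * e + sqrt(max(0, 1 - cl$r^2)) * stats::rnorm(nSubjects)
    } else stats::rnorm(nSubjects)
    score <- pmin(79, pmax(10, 44.66 + 17.96 * z))
    duration <- ifelse(groups == "TS", stats::runif(nSubjects, 1, 12), 0)
    data.frame(subject_id = subjectIds, group = groups, score = score,
               duration_months = duration, stringsAsFactors = FALSE)
  })

  # jitter-block geometry
  stepTrs <- as.integer(round((1 - ivaOverlap) * ivaWindowTrs))
  nBlocks <- if (spatialJitter > 0) {
    if (stepTrs < 1L || T %% stepTrs != 0L)
      stop("nTimepoints must be divisible by the jitter block length")
    T %/% stepTrs
  } else 1L

  series <- vector("list", nSubjects)
  stateSeqs <- vector("list", nSubjects)
  tcs <- vector("list", nSubjects)
  jit <- vector("list", nSubjects)
  for (m in seq_len(nSubjects)) {
    st <- generateStateTimecourses(T, subjCov[[m]], dwellMeanTrs,
                                   seed = childSeed(seed, 100L + m))
    stateSeqs[[m]] <- st$stateSequence
    tcs[[m]] <- st$timeCourses
    X <- withSeed(childSeed(seed, 200L + m), {
      if (spatialJitter > 0) {
        fields <- lapply(seq_len(nBlocks), function(b) {
          mod <- vapply(seq_len(nSources), function(n)
            1 + spatialJitter * smoothField(maskCoords, gridShape),
            numeric(V))
          t(mod)                              # N x V modulation
        })
        jit[[m]] <- fields
        X <- matrix(0, T, V)
        for (b in seq_len(nBlocks)) {
          rows <- ((b - 1L) * stepTrs + 1L):(b * stepTrs)
          X[rows, ] <- st$timeCourses[rows, , drop = FALSE] %*%
            (S * fields[[b]])
        }
        X
      } else {
        jit[[m]] <- list()
        st$timeCourses %*% S
      }
    })
    if (is.finite(snr)) {
      X <- X + withSeed(childSeed(seed, 300L + m), {
        noiseSd <- sqrt(stats::var(as.vector(X)) / snr)
        matrix(stats::rnorm(length(X), 0, noiseSd), nrow(X), ncol(X))
      })
    }
    series[[m]] <- BoldSeries(X, trSeconds = trSeconds,
                              maskIndices = src$maskIndices,
                              gridShape = gridShape,
                              subjectId = subjectIds[m])
  }

  truth <- new("GroundTruth",
               spatialSources = S,
               maskIndices = as.integer(src$maskIndices),
               gridShape = as.integer(gridShape),
               stateCovariances = stateCovariances,
               subjectCovariances = subjCov,
               stateSequences = stateSeqs,
               timeCourses = tcs,
               jitterFields = jit,
               clinicalTable = clin,
               plantedEffects = plantedEffects,
               genParams = list(nTimepoints = T, snr = snr,
                                spatialJitter = spatialJitter,
                                dwellMeanTrs = dwellMeanTrs,
                                trSeconds = trSeconds,
                                ivaWindowTrs = ivaWindowTrs,
                                ivaOverlap = ivaOverlap,
                                blockTrs = stepTrs,
                                realizedClinicalEdge = realizedEdge),
               seed = as.integer(seed))
  list(series = series, truth = truth)
}

#' Ground-truth mixing matrix for one (subject, window) dataset
#'
#' Returns the rows of subject \code{m}'s source time courses covered by IVA
#' window \code{l}: the T_w x N mixing matrix of that windowed dataset.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param m subject index.
#' @param l window index (1-based).
#' @return T_w x N numeric matrix.
#' @export
groundTruthMixing <- function(truth, m, l) {
  p <- truth@genParams
  step <- as.integer(round((1 - p$ivaOverlap) * p$ivaWindowTrs))
  rows <- ((l - 1L) * step + 1L):((l - 1L) * step + p$ivaWindowTrs)
  truth@timeCourses[[m]][rows, , drop = FALSE]
}

#' Ground-truth source maps for one (subject, window) dataset
#'
#' The shared sources as modulated in window \code{l} for subject \code{m}
#' (average of the window's jitter blocks); the shared maps when jitter is 0.
#'
#' @inheritParams groundTruthMixing
#' @return N x V numeric matrix.
#' @export
groundTruthWindowMaps <- function(truth, m, l) {
  S <- truth@spatialSources
  if (length(truth@jitterFields[[m]]) == 0L) return(S)
  p <- truth@genParams
  blocksPerWin <- p$ivaWindowTrs %/% p$blockTrs
  blocks <- (l - 1L) + seq_len(blocksPerWin)
  mod <- Reduce(`+`, truth@jitterFields[[m]][blocks]) / blocksPerWin
  S * mod
}

#' Write a synthetic dataset to disk
#'
#' Writes one 4-D NIfTI volume per subject, the 3-D mask, the ground-truth
#' source maps as a 4-D NIfTI, and the clinical table as CSV with header
#' \code{subject_id,group,score,duration_months}.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named list).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- dataset$truth
  gs <- truth@gridShape
  mask <- array(0L, gs)
  mask[truth@maskIndices] <- 1L
  maskPath <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(mask, maskPath)
  paths <- list(mask = maskPath)
  for (s in dataset$series) {
    vol <- array(0, c(gs, nrow(s@data)))
    flat <- matrix(0, prod(gs), nrow(s@data))
    flat[s@maskIndices, ] <- t(s@data)
    vol[] <- flat
    p <- file.path(dir, paste0(s@subjectId, ".nii.gz"))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(1, 1, 1, s@trSeconds)
    RNifti::writeNifti(img, p, datatype = "float")
    paths[[s@subjectId]] <- p
  }
  srcPath <- file.path(dir, "true_sources.nii.gz")
  saveComponentMaps(truth@spatialSources, truth@maskIndices, gs, srcPath)
  clinPath <- file.path(dir, "clinical.csv")
  utils::write.csv(truth@clinicalTable, clinPath, row.names = FALSE)
  paths$sources <- srcPath
  paths$clinical <- clinPath
  invisible(paths)
}
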