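# Independent vector analysis over windowed multi-subject data.
#
# Each (subject m, window l) dataset X^[m,l] (T_w x V, voxels as samples) is
# modeled as A^[m,l] s^[m,l] with N independent sources. IVA estimates all
# M x L demixing matrices jointly so that the n-th source component vector
# (SCV) -- row n collected across every dataset -- is maximally independent of
# the others while its members stay mutually dependent, which keeps component
# order aligned across datasets. IVA-G models SCVs as multivariate Gaussian
# (second-order statistics); IVA-L as multivariate Laplacian (higher-order);
# IVA-GL refines the IVA-G solution under the Laplacian prior.

#' Segment a BOLD series into overlapping windows
#'
#' Window l (0-based) covers TRs \code{[l*step, l*step + windowTrs)} with
#' \code{step = (1 - overlapFraction) * windowTrs}; the segmentation must tile
#' the series exactly (the last window ends at T). Each voxel is demeaned
#' within each window by default ("demean"); "voxel" additionally scales every
#' voxel to unit variance within the window (this reshapes the spatial maps
#' the decomposition estimates and degrades map fidelity, so it is not the
#' default); "none" leaves the data untouched.
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param windowTrs window length t in TRs (paper-scale default 48).
#' @param overlapFraction fractional overlap in [0, 1) (default 0.5).
#' @param normalize one of "demean" (default), "voxel", "none".
#' @return A \linkS4class{WindowSegmentation} with
#'   \code{L = (T - windowTrs)/step + 1} windows.
#' @export
segmentWindows <- function(series, windowTrs = 48L, overlapFraction = 0.5,
                           normalize = c("demean", "voxel", "none")) {
  normalize <- if (isTRUE(normalize)) "voxel" else if (isFALSE(normalize))
    "demean" else match.arg(normalize)
  stopifnot(overlapFraction >= 0, overlapFraction < 1)
  windowTrs <- as.integer(windowTrs)
  step <- (1 - overlapFraction) * windowTrs
  if (abs(step - round(step)) > 1e-9 || round(step) < 1)
    stop(sprintf("(1 - overlap) x window = %.3f TRs is not a positive integer; choose e.g. overlap 0.5 with an even window",
                 step))
  step <- as.integer(round(step))
  Tlen <- nrow(series@data)
  if ((Tlen - windowTrs) %% step != 0L)
    stop(sprintf("T = %d cannot be tiled by %d-TR windows at step %d; (T - window) must be divisible by the step (valid T near this one: %d or %d)",
                 Tlen, windowTrs, step,
                 windowTrs + step * ((Tlen - windowTrs) %/% step),
                 windowTrs + step * ((Tlen - windowTrs) %/% step + 1L)))
  L <- (Tlen - windowTrs) %/% step + 1L
  starts <- (seq_len(L) - 1L) * step
  wins <- lapply(seq_len(L), function(l) {
    seg <- series@data[(starts[l] + 1L):(starts[l] + windowTrs), , drop = FALSE]
    if (normalize != "none")
      seg <- seg - matrix(colMeans(seg), nrow(seg), ncol(seg), byrow = TRUE)
    if (normalize == "voxel") {
      sds <- sqrt(colSums(seg^2) / (nrow(seg) - 1L))
      seg <- seg / matrix(pmax(sds, 1e-12), nrow(seg), ncol(seg), byrow = TRUE)
    }
    seg
  })
  new("WindowSegmentation", windows = wins, windowLengthTrs = windowTrs,
      nWindows = L, overlapFraction = overlapFraction,
      startIndices = as.integer(starts), subjectId = series@subjectId)
}

# Shared IVA engine. scoreFun(Ystack, n) must return the N x V score matrix
# contribution and the cost term for SCV n given its K x V member stack.
# Natural-gradient updates with backtracking keep the cost non-increasing.
ivaEngine <- function(datasets, nComponents, W0 = NULL, seed = 1,
                      prior = c("gauss", "laplace"), maxIter = 1024L,
                      tol = 1e-6) {
  prior <- match.arg(prior)
  K <- length(datasets)
  stopifnot(K >= 2L)
  V <- ncol(datasets[[1]])
  for (d in datasets) if (ncol(d) != V) stop("all datasets must share V")
  if (nComponents > min(vapply(datasets, nrow, integer(1))))
    stop("nComponents exceeds the smallest dataset row count")
  N <- as.integer(nComponents)
  wh <- lapply(datasets, whitenRows, nc = N, center = FALSE)
  Z <- lapply(wh, `[[`, "Z")                     # K of N x V, cov = I
  # one shared random init keeps the datasets' solutions aligned from the
  # start (they are views of the same sources), avoiding permutation traps
  W <- if (is.null(W0)) {
    W0c <- withSeed(seed, randomOrthonormal(N))
    lapply(seq_len(K), function(k) W0c)
  } else W0
  eps <- 1e-12

  evalState <- function(W) {
    Y <- lapply(seq_len(K), function(k) W[[k]] %*% Z[[k]])
    cost <- -sum(vapply(W, function(w) determinant(w)$modulus, numeric(1)))
    Phi <- lapply(seq_len(K), function(k) matrix(0, N, V))
    for (n in seq_len(N)) {
      Yn <- do.call(rbind, lapply(Y, function(y) y[n, ]))   # K x V
      if (prior == "gauss") {
        Sn <- tcrossprod(Yn) / V
        Sn <- Sn + diag(1e-9 * mean(diag(Sn)) + 1e-12, K)
        cost <- cost + 0.5 * determinant(Sn)$modulus
        Pn <- solve(Sn, Yn)                                  # K x V scores
      } else {
        nrm <- sqrt(colSums(Yn^2))
        cost <- cost + mean(nrm)
        Pn <- Yn / matrix(pmax(nrm, eps), K, V, byrow = TRUE)
      }
      for (k in seq_len(K)) Phi[[k]][n, ] <- Pn[k, ]
    }
    list(Y = Y, Phi = Phi, cost = as.numeric(cost))
  }

  st <- evalState(W)
  eta <- 0.1
  converged <- FALSE
  it <- 0L
  gradNorm <- Inf
  while (it < maxIter) {
    it <- it + 1L
    G <- lapply(seq_len(K), function(k) {
      if (prior == "gauss") diag(N) - st$Phi[[k]] %*% t(st$Y[[k]]) / V
      else diag(N) - st$Phi[[k]] %*% t(st$Y[[k]]) / V
    })
    gradNorm <- max(vapply(G, function(g) max(abs(g)), numeric(1)))
    if (gradNorm < tol) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in seq_len(30L)) {
      Wn <- lapply(seq_len(K), function(k) W[[k]] + eta * G[[k]] %*% W[[k]])
      ok <- all(vapply(Wn, function(w) all(is.finite(w)) &&
                         abs(det(w)) > 1e-12, logical(1)))
      if (ok) {
        stn <- evalState(Wn)
        if (is.finite(stn$cost) && stn$cost <= st$cost + 1e-12) {
          W <- Wn; st <- stn; accepted <- TRUE
          break
        }
      }
      eta <- eta / 2
    }
    if (!accepted) break                        # cannot decrease further
    if (bt == 1L) eta <- min(eta * 1.2, 1)
  }
  list(W = W, whitening = lapply(wh, `[[`, "whitening"),
       demixing = lapply(seq_len(K), function(k) W[[k]] %*% wh[[k]]$whitening),
       sources = st$Y, cost = st$cost, converged = converged,
       iterations = it, gradNorm = gradNorm)
}

#' IVA with a multivariate Gaussian SCV prior (IVA-G)
#'
#' Natural-gradient minimization of the IVA maximum-likelihood cost
#' \code{sum_n 1/2 log det Sigma_n - sum_k log |det W^(k)|} (Sigma_n = sample
#' covariance of SCV n across datasets), after per-dataset whitening to
#' \code{nComponents}. A backtracking line search keeps the cost
#' non-increasing; iteration stops when the natural-gradient norm falls below
#' \code{tol}.
#'
#' @param datasets list of T_w x V matrices sharing V (>= 2 datasets).
#' @param nComponents number of sources N (<= smallest row count).
#' @param seed integer seed for the random orthonormal initialization.
#' @param maxIter,tol iteration cap (default 1024) and gradient tolerance
#'   (default 1e-6).
#' @return list with \code{demixing} (per dataset N x T_w, whitening
#'   included), \code{W} (square unmixing in whitened space),
#'   \code{whitening}, \code{sources} (per dataset N x V), \code{cost},
#'   \code{converged}, \code{iterations}.
#' @export
ivaG <- function(datasets, nComponents, seed = 1, maxIter = 1024L,
                 tol = 1e-6) {
  res <- ivaEngine(datasets, nComponents, W0 = NULL, seed = seed,
                   prior = "gauss", maxIter = maxIter, tol = tol)
  if (!res$converged && res$gradNorm > 1e-3)
    warning(sprintf("ivaG stopped after %d iterations with gradient norm %.2e",
                    res$iterations, res$gradNorm))
  res
}

#' IVA with a multivariate Laplacian SCV prior (IVA-L)
#'
#' As [ivaG()] but minimizing the multivariate-Laplacian cost
#' \code{sum_n E[||y_n||_2] - sum_k log |det W^(k)|} whose score exploits
#' higher-order statistics. Starts from \code{initDemixing} when provided
#' (e.g. an IVA-G solution), else from a seeded random orthonormal matrix per
#' dataset.
#'
#' @inheritParams ivaG
#' @param initDemixing optional list of square N x N unmixing matrices in
#'   whitened space (the \code{W} element of an [ivaG()] result).
#' @return As [ivaG()].
#' @export
ivaL <- function(datasets, nComponents, initDemixing = NULL, seed = 1,
                 maxIter = 1024L, tol = 1e-6) {
  if (!is.null(initDemixing)) {
    stopifnot(length(initDemixing) == length(datasets))
    for (w in initDemixing)
      stopifnot(nrow(w) == nComponents, ncol(w) == nComponents)
  }
  res <- ivaEngine(datasets, nComponents, W0 = initDemixing, seed = seed,
                   prior = "laplace", maxIter = maxIter, tol = tol)
  if (!res$converged && res$gradNorm > 1e-3)
    warning(sprintf("ivaL stopped after %d iterations with gradient norm %.2e",
                    res$iterations, res$gradNorm))
  res
}

#' IVA-GL joint decomposition of windowed multi-subject data
#'
#' Flattens the per-subject window segmentations into M x L datasets, runs
#' [ivaG()], refines its solution with [ivaL()], and assembles the result as
#' an \linkS4class{SCVSet}: row n of every (subject, window) source matrix is
#' one spatially dynamic component (SDC), and the collection of row n across
#' datasets is SCV n.
#'
#' @param segmentations list of per-subject \linkS4class{WindowSegmentation}
#'   objects sharing V and L.
#' @param nComponents number of components N (paper-scale default 20).
#' @param seed integer seed.
#' @param maxIter,tol passed to both IVA stages.
#' @return An \linkS4class{SCVSet}.
#' @export
ivaGL <- function(segmentations, nComponents = 20L, seed = 1,
                  maxIter = 1024L, tol = 1e-6) {
  stopifnot(length(segmentations) >= 1L)
  L <- segmentations[[1]]@nWindows
  V <- ncol(segmentations[[1]]@windows[[1]])
  for (sg in segmentations) {
    if (sg@nWindows != L) stop("subjects have inconsistent window counts L")
    if (ncol(sg@windows[[1]]) != V) stop("subjects have inconsistent V")
  }
  M <- length(segmentations)
  datasets <- vector("list", M * L)
  idx <- data.frame(dataset = seq_len(M * L),
                    subject = rep(seq_len(M), each = L),
                    window = rep(seq_len(L), times = M))
  for (r in seq_len(nrow(idx)))
    datasets[[r]] <- segmentations[[idx$subject[r]]]@windows[[idx$window[r]]]
  g <- ivaG(datasets, nComponents, seed = seed, maxIter = maxIter, tol = tol)
  l <- ivaL(datasets, nComponents, initDemixing = g$W, seed = seed,
            maxIter = maxIter, tol = tol)
  names(l$demixing) <- names(l$sources) <-
    sprintf("m%02d_l%02d", idx$subject, idx$window)
  new("SCVSet", demixing = l$demixing, sources = l$sources,
      datasetIndex = idx, nComponents = as.integer(nComponents),
      converged = c(ivaG = g$converged, ivaL = l$converged))
}

#' Screen SDCs against templates and keep the best-matching components
#'
#' Ranks components by the best absolute template correlation of their
#' sign-aligned SCV-mean map and keeps the top \code{keep} (an automated
#' stand-in for visual artifact inspection). Component order within the kept
#' set follows the original component indices.
#'
#' @param scvset an \linkS4class{SCVSet}.
#' @param templates named map matrix or list as in [labelComponents()].
#' @param keep number of components to retain (default 9).
#' @return list with \code{scvset} (reduced \linkS4class{SCVSet}),
#'   \code{kept} (original component indices), \code{ranking} (data.frame:
#'   component, template, r).
#' @export
screenSDCs <- function(scvset, templates, keep = 9L) {
  stopifnot(keep >= 1L, keep <= scvset@nComponents)
  if (is.list(templates)) templates <- do.call(rbind, templates)
  if (is.null(rownames(templates)))
    rownames(templates) <- sprintf("template%02d", seq_len(nrow(templates)))
  means <- scvMeanMaps(scvset)
  R <- stats::cor(t(means), t(templates))
  best <- apply(abs(R), 1L, which.max)
  bestR <- abs(R)[cbind(seq_len(nrow(means)), best)]
  kept <- sort(order(bestR, decreasing = TRUE)[seq_len(keep)])
  sources <- lapply(scvset@sources, function(s) s[kept, , drop = FALSE])
  demix <- lapply(scvset@demixing, function(w) w[kept, , drop = FALSE])
  list(scvset = new("SCVSet", demixing = demix, sources = sources,
                    datasetIndex = scvset@datasetIndex,
                    nComponents = as.integer(keep),
                    converged = scvset@converged),
       kept = kept,
       ranking = data.frame(component = seq_len(nrow(means)),
                            template = rownames(templates)[best], r = bestR))
}

#' Sign-aligned mean map of every SCV
#'
#' Averages each component's source maps over all (subject, window) datasets
#' after aligning their signs to the first dataset's map.
#'
#' @param scvset an \linkS4class{SCVSet}.
#' @return N x V matrix of mean maps.
#' @export
scvMeanMaps <- function(scvset) {
  N <- scvset@nComponents
  t(vapply(seq_len(N), function(n) {
    stack <- scvMatrix(scvset, n)
    ref <- stack[1, ]
    sgn <- sign(as.numeric(stack %*% ref))
    sgn[sgn == 0] <- 1
    colMeans(stack * sgn)
  }, numeric(ncol(scvset@sources[[1]]))))
}
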