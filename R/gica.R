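# Temporal-concatenation group ICA.
#
# Subject data are PCA-reduced in the time dimension, concatenated in time,
# reduced once more by a group PCA, and decomposed by extended Infomax ICA.
# ICASSO reruns the ICA from many seeds and clusters the estimates to obtain
# stable components; subject maps and time courses are recovered by dual
# (spatial-temporal) regression.

#' Subject-level PCA reduction and temporal concatenation
#'
#' Per subject, voxel means are removed and the time dimension is reduced to
#' \code{nSubjectPCs} principal components (eigenvectors of the T x T data
#' covariance across voxels); each reduced matrix is scaled to unit mean
#' variance so no subject dominates the group stage by raw intensity (this
#' also makes the chain exactly invariant to per-subject scalar rescaling);
#' the matrices are stacked row-wise and reduced again to \code{nGroupPCs}
#' rows by a group PCA. The reduction operators are retained for
#' back-reconstruction.
#'
#' @param series list of \linkS4class{BoldSeries} sharing the mask.
#' @param nSubjectPCs per-subject retained components (<= min(T, V)).
#' @param nGroupPCs group-level retained components (<= M * nSubjectPCs and
#'   <= numerical rank of the concatenated matrix).
#' @return list with \code{groupData} (nGroupPCs x V), \code{groupOperator}
#'   ((M*nSubjectPCs) x nGroupPCs eigenvector matrix), \code{subjectOperators}
#'   (per-subject T x nSubjectPCs eigenvector matrices), \code{subjectMeans}
#'   (per-subject voxel mean vectors), \code{subjectIds}, \code{eigenvalues}
#'   (group PCA spectrum).
#' @export
reduceAndConcat <- function(series, nSubjectPCs, nGroupPCs) {
  stopifnot(length(series) >= 1L)
  V <- ncol(series[[1]]@data)
  M <- length(series)
  Tlen <- nrow(series[[1]]@data)
  if (nSubjectPCs > min(Tlen, V))
    stop("nSubjectPCs exceeds min(T, V)")
  if (nGroupPCs > nSubjectPCs * M)
    stop("nGroupPCs exceeds the concatenated row count")
  subjectOperators <- vector("list", M)
  subjectMeans <- vector("list", M)
  reduced <- vector("list", M)
  for (m in seq_len(M)) {
    X <- series[[m]]@data
    if (ncol(X) != V) stop("all subjects must share the mask (V mismatch)")
    mu <- colMeans(X)
    Xc <- X - matrix(mu, nrow(X), V, byrow = TRUE)
    C <- tcrossprod(Xc) / V
    e <- eigen(C, symmetric = TRUE)
    U <- e$vectors[, seq_len(nSubjectPCs), drop = FALSE]
    subjectOperators[[m]] <- U
    subjectMeans[[m]] <- mu
    R <- crossprod(U, Xc)                     # nSubjectPCs x V
    reduced[[m]] <- R / sqrt(mean(R^2))       # unit mean variance per subject
  }
  concat <- do.call(rbind, reduced)
  Cg <- tcrossprod(concat) / V
  eg <- eigen(Cg, symmetric = TRUE)
  rank <- sum(eg$values > 1e-10 * max(eg$values))
  if (nGroupPCs > rank)
    stop(sprintf("nGroupPCs = %d exceeds the concatenated rank (%d)",
                 nGroupPCs, rank))
  G <- eg$vectors[, seq_len(nGroupPCs), drop = FALSE]
  list(groupData = crossprod(G, concat),
       groupOperator = G,
       subjectOperators = subjectOperators,
       subjectMeans = subjectMeans,
       subjectIds = vapply(series, function(s) s@subjectId, character(1)),
       eigenvalues = eg$values[seq_len(nGroupPCs)])
}

#' Extended Infomax independent component analysis
#'
#' Full-batch natural-gradient extended Infomax with a monotone line search:
#' the data are whitened to \code{nComponents} rows and the unmixing matrix
#' is updated along \code{(I - K tanh(U) U'/V - U U'/V) W}, where \code{K} is
#' the per-component sub/super-Gaussian switch
#' \code{sign(E[sech^2 u] E[u^2] - E[u tanh u])}. Each step is accepted only
#' if it does not decrease the matching log-likelihood
#' \code{log |det W| + sum_n E[-u_n^2/2 - k_n log cosh u_n]} (backtracking
#' halves the step otherwise), which prevents the limit cycles plain
#' annealed gradient infomax can fall into. Iteration stops when the
#' natural-gradient norm falls below \code{tol}.
#'
#' @param X numeric matrix, rows = channels (>= nComponents), columns =
#'   samples; whitened internally.
#' @param nComponents number of components to extract.
#' @param seed integer seed for the random orthonormal initial unmixing.
#' @param maxIter maximum iterations (default 2048).
#' @param tol convergence tolerance on the max absolute natural-gradient
#'   entry (default 1e-6).
#' @param lrate initial step size (default 0.1; adapted by the line search).
#' @return list with \code{components} (nComponents x V), \code{unmixing}
#'   (nComponents x nrow(X), whitening included), \code{W} (square unmixing
#'   in whitened space), \code{whitening}, \code{converged},
#'   \code{iterations}, \code{kurtosisSign}, \code{logLik}.
#' @export
infomaxICA <- function(X, nComponents, seed = 1, maxIter = 2048L,
                       tol = 1e-6, lrate = 0.1) {
  stopifnot(nrow(X) >= nComponents)
  wh <- whitenRows(X, nComponents)
  Z <- wh$Z
  N <- nComponents
  Vn <- ncol(Z)
  loglik <- function(W, kS) {
    U <- W %*% Z
    as.numeric(determinant(W)$modulus) +
      mean(colSums(-U^2 / 2 - kS * log(cosh(U))))
  }
  withSeed(seed, {
    W <- randomOrthonormal(N)
    converged <- FALSE
    it <- 0L
    kSign <- rep(1, N)
    gnorm <- Inf
    while (it < maxIter) {
      it <- it + 1L
      U <- W %*% Z
      tu <- tanh(U)
      kSign <- sign(rowMeans(1 - tu^2) * rowMeans(U^2) - rowMeans(U * tu))
      kSign[kSign == 0] <- 1
      grad <- diag(N) - ((kSign * tu) %*% t(U) + U %*% t(U)) / Vn
      gnorm <- max(abs(grad))
      if (gnorm < tol) { converged <- TRUE; break }
      cur <- loglik(W, kSign)
      accepted <- FALSE
      for (bt in seq_len(25L)) {
        Wn <- W + lrate * grad %*% W
        if (all(is.finite(Wn)) && abs(det(Wn)) > 1e-12 &&
            loglik(Wn, kSign) > cur - 1e-12) { accepted <- TRUE; break }
        lrate <- lrate / 2
      }
      if (!accepted) break
      W <- Wn
      if (bt == 1L) lrate <- min(lrate * 1.2, 1)
    }
    if (!converged)
      warning(sprintf("infomaxICA did not converge in %d iterations (gradient norm %.2e)",
                      it, gnorm))
    comps <- W %*% Z
    list(components = comps, unmixing = W %*% wh$whitening, W = W,
         whitening = wh$whitening, converged = converged, iterations = it,
         kurtosisSign = kSign, logLik = loglik(W, kSign))
  })
}

#' ICASSO stability selection
#'
#' Runs [infomaxICA()] \code{nRuns} times from distinct seeds, pools the
#' estimated component maps, clusters them by absolute Pearson correlation
#' (average-linkage agglomerative clustering cut at \code{nComponents}
#' clusters), and represents each cluster by its centrotype (the member with
#' the largest within-cluster similarity sum). The stability index of a
#' cluster is \code{iq = mean intra-cluster similarity - mean extra-cluster
#' similarity}. Clusters with fewer than \code{minClusterSize} members are
#' kept but flagged unstable.
#'
#' @param X reduced group data matrix (rows >= nComponents).
#' @param nComponents number of components / clusters.
#' @param nRuns number of ICA restarts (paper-scale default 100).
#' @param minClusterSize minimum members for a stable cluster (default 80).
#' @param seed master seed; run r uses a seed derived from (seed, r).
#' @param seeds optional explicit length-nRuns seed vector (overrides
#'   \code{seed}-derived seeds; repeats allowed, e.g. to check that identical
#'   runs give iq ~ 1).
#' @return list with \code{components} (a \linkS4class{ComponentSet} whose maps
#'   are the z-scaled centrotypes, skew-positive sign convention) and
#'   \code{clusterInfo} (data.frame: component, size, iq, stable).
#' @export
icassoSelect <- function(X, nComponents, nRuns = 100L, minClusterSize = 80L,
                         seed = 1, seeds = NULL) {
  stopifnot(nRuns >= 2L, minClusterSize <= nRuns)
  if (is.null(seeds)) seeds <- vapply(seq_len(nRuns),
                                      function(r) childSeed(seed, 1000L + r),
                                      integer(1))
  stopifnot(length(seeds) == nRuns)
  runs <- lapply(seeds, function(s)
    suppressWarnings(infomaxICA(X, nComponents, seed = s)))
  pool <- do.call(rbind, lapply(runs, `[[`, "components"))
  sim <- abs(stats::cor(t(pool)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = nComponents)
  info <- lapply(seq_len(nComponents), function(c) {
    idx <- which(cl == c)
    inSim <- sim[idx, idx, drop = FALSE]
    intra <- if (length(idx) > 1L) mean(inSim[upper.tri(inSim)]) else 1
    extra <- mean(sim[idx, -idx, drop = FALSE])
    cent <- idx[which.max(rowSums(inSim))]
    list(size = length(idx), iq = intra - extra, centrotype = cent)
  })
  ord <- order(vapply(info, `[[`, integer(1), "size"),
               vapply(info, `[[`, numeric(1), "iq"),
               decreasing = TRUE)
  info <- info[ord]
  maps <- do.call(rbind, lapply(info, function(i) pool[i$centrotype, , drop = FALSE]))
  maps <- zScaleRows(maps)
  # sign convention: positive skewness per map
  sk <- rowMeans(maps^3)
  maps <- maps * ifelse(sk < 0, -1, 1)
  iq <- vapply(info, `[[`, numeric(1), "iq")
  sizes <- vapply(info, `[[`, integer(1), "size")
  stable <- sizes >= minClusterSize
  if (any(!stable))
    warning(sprintf("%d component cluster(s) below the minimum size %d; kept but flagged unstable",
                    sum(!stable), minClusterSize))
  list(components = ComponentSet(maps, stabilityIq = pmin(pmax(iq, 0), 1)),
       clusterInfo = data.frame(component = seq_len(nComponents),
                                size = sizes, iq = iq, stable = stable))
}

#' Back-reconstruct subject maps and time courses by dual regression
#'
#' Stage 1 regresses the group spatial maps onto each subject's data to get
#' subject time courses (T x N); stage 2 regresses those time courses onto the
#' data to get subject spatial maps (N x V). Subject maps are sign-aligned to
#' the group maps.
#'
#' @param groupComponents a \linkS4class{ComponentSet} (or N x V matrix) of
#'   group spatial maps.
#' @param reduction result of [reduceAndConcat()] on the same subjects (used
#'   for the subject list; dual regression operates on the original data).
#' @param series list of \linkS4class{BoldSeries}, same subjects and order as
#'   in \code{reduction}.
#' @return list of per-subject \linkS4class{ComponentSet}s, each with the
#'   subject's maps (z-scaled) and a one-element \code{timeCourses} list.
#' @export
backReconstruct <- function(groupComponents, reduction = NULL, series) {
  maps <- if (methods::is(groupComponents, "ComponentSet"))
    groupComponents@spatialMaps else as.matrix(groupComponents)
  if (!is.null(reduction)) {
    ids <- vapply(series, function(s) s@subjectId, character(1))
    if (!identical(ids, reduction$subjectIds))
      stop("subject list does not match the reduction operators")
  }
  N <- nrow(maps)
  lapply(series, function(s) {
    X <- s@data
    if (ncol(X) != ncol(maps)) stop("map/voxel dimension mismatch")
    Xc <- X - matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
    SSt <- tcrossprod(maps)
    tc <- Xc %*% t(maps) %*% solve(SSt)                   # T x N
    sm <- solve(crossprod(tc), crossprod(tc, Xc))         # N x V
    # align subject map signs to group maps; flip time course together
    sgn <- sign(vapply(seq_len(N), function(n)
      stats::cor(sm[n, ], maps[n, ]), numeric(1)))
    sgn[sgn == 0 | is.na(sgn)] <- 1
    sm <- sm * sgn
    tc <- tc * matrix(sgn, nrow(tc), N, byrow = TRUE)
    sds <- apply(sm, 1L, stats::sd)
    sm <- (sm - rowMeans(sm)) / ifelse(sds > 0, sds, 1)
    ComponentSet(sm, timeCourses = stats::setNames(list(tc), s@subjectId))
  })
}

#' Label components against spatial templates and screen artifacts
#'
#' Each component map is correlated with every template map; the best-matching
#' template (highest absolute Pearson r, ties broken by template order) names
#' the component if the correlation reaches \code{artifactRThreshold},
#' otherwise the component is labeled "artifact". If a gray-matter mask is
#' supplied, components whose in-gray-matter energy fraction (sum of squared
#' map values) is below 0.5 are also labeled "artifact".
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param templates named N_t x V matrix (rows = templates) or named list of
#'   length-V vectors, on the same mask.
#' @param artifactRThreshold minimum |r| for a network label (default 0.2).
#' @param grayMatterMask optional length-V logical/0-1 vector.
#' @return the \linkS4class{ComponentSet} with \code{labels} and
#'   \code{templateCorrelations} filled in.
#' @export
labelComponents <- function(components, templates, artifactRThreshold = 0.2,
                            grayMatterMask = NULL) {
  if (is.list(templates)) templates <- do.call(rbind, templates)
  if (is.null(rownames(templates)))
    rownames(templates) <- sprintf("template%02d", seq_len(nrow(templates)))
  if (nrow(templates) == 0L) stop("empty template set")
  maps <- components@spatialMaps
  if (ncol(templates) != ncol(maps))
    stop("templates and components must share the mask")
  R <- stats::cor(t(maps), t(templates))       # N x N_t
  best <- apply(abs(R), 1L, which.max)         # first max wins ties
  bestR <- abs(R)[cbind(seq_len(nrow(maps)), best)]
  labels <- ifelse(bestR >= artifactRThreshold,
                   rownames(templates)[best], "artifact")
  if (!is.null(grayMatterMask)) {
    gm <- as.logical(grayMatterMask)
    if (length(gm) != ncol(maps)) stop("gray-matter mask length must equal V")
    frac <- rowSums(maps[, gm, drop = FALSE]^2) / rowSums(maps^2)
    labels[frac < 0.5] <- "artifact"
  }
  components@labels <- labels
  components@templateCorrelations <- data.frame(
    component = seq_len(nrow(maps)),
    template = rownames(templates)[best],
    r = bestR)
  methods::validObject(components)
  components
}
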