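# Shared numerical helpers.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; kept below 2^31.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483629)
}

#' Fisher z-transform and its inverse
#'
#' \code{fisherZ} maps correlations to atanh(r) (values clipped to +-(1 - 1e-12)
#' first so r = +-1 stays finite); \code{fisherZinv} maps back with tanh.
#'
#' @param r correlations in [-1, 1].
#' @param z Fisher-z values.
#' @return transformed numeric vector/matrix of the same shape.
#' @export
fisherZ <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' @rdname fisherZ
#' @export
fisherZinv <- function(z) tanh(z)

# Vectorize the upper triangle (i < j, column-major order) of a symmetric matrix.
upperTriVec <- function(m) m[upper.tri(m)]

# Edge (i, j) pairs in the order produced by upperTriVec for an N x N matrix.
edgePairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Rebuild a symmetric matrix (unit or zero diagonal) from an upper-tri vector.
vecToSym <- function(v, n, diagVal = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diagVal
  m
}

# z-scale each row of a matrix (mean 0, sd 1); errors on constant rows.
zScaleRows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  if (any(sd == 0)) stop("cannot z-scale a constant row")
  (m - mu) / sd
}

#' Amari index of a gain matrix
#'
#' Permutation- and scale-invariant distance between an estimated unmixing and
#' the true mixing: \code{amariIndex(W %*% A)} is 0 iff W A is a scaled
#' permutation, and approaches 1 for unrelated matrices (normalized to [0, 1]).
#'
#' @param G square gain matrix (typically unmixing times true mixing).
#' @return scalar in [0, 1].
#' @export
amariIndex <- function(G) {
  G <- abs(G)
  n <- nrow(G)
  rowTerm <- sum(rowSums(G) / apply(G, 1L, max) - 1)
  colTerm <- sum(colSums(G) / apply(G, 2L, max) - 1)
  (rowTerm + colTerm) / (2 * n * (n - 1))
}

#' Joint inter-symbol interference across datasets
#'
#' Average-gain joint ISI for a joint blind source separation solution: the
#' Amari-style index of the mean absolute gain matrix across datasets. Zero
#' means every dataset is separated with a single consistent permutation; a
#' per-dataset permutation mismatch inflates it even when each dataset is
#' individually separated.
#'
#' @param gains list of square gain matrices W^(k) A^(k), one per dataset.
#' @return scalar in [0, 1].
#' @export
jointISI <- function(gains) {
  stopifnot(length(gains) >= 1L)
  Gbar <- Reduce(`+`, lapply(gains, abs)) / length(gains)
  amariIndex(Gbar)
}

#' Match estimated components to reference components
#'
#' One-to-one assignment maximizing the total absolute correlation between
#' rows of \code{est} and rows of \code{ref}. Exhaustive over permutations for
#' n <= 7, greedy otherwise.
#'
#' @param est N x V matrix of estimated maps (rows).
#' @param ref N x V matrix of reference maps (rows).
#' @return list with \code{perm} (perm[i] = reference row matched to estimated
#'   row i), \code{r} (signed correlation per matched pair) and \code{meanAbsR}.
#' @export
matchComponents <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  n <- nrow(est)
  R <- stats::cor(t(est), t(ref))   # n x n signed correlations
  A <- abs(R)
  if (n <= 7L) {
    perms <- permutationsAll(n)
    best <- NULL; bestScore <- -Inf
    for (k in seq_len(nrow(perms))) {
      p <- perms[k, ]
      sc <- sum(A[cbind(seq_len(n), p)])
      if (sc > bestScore) { bestScore <- sc; best <- p }
    }
    perm <- best
  } else {
    perm <- integer(n)
    usedRef <- logical(n)
    ord <- order(apply(A, 1L, max), decreasing = TRUE)
    for (i in ord) {
      cand <- which(!usedRef)
      j <- cand[which.max(A[i, cand])]
      perm[i] <- j
      usedRef[j] <- TRUE
    }
  }
  perm <- unname(perm)
  r <- unname(R[cbind(seq_len(n), perm)])
  list(perm = perm, r = r, meanAbsR = mean(abs(r)))
}

permutationsAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsAll(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): returns k rows of x as centers.
kmeansPPInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[i + 1L, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

# Whiten rows of X to nc components: returns Z (nc x V) with sample covariance
# exactly I, plus the whitening (nc x n) and dewhitening (n x nc) operators.
# center = FALSE whitens the raw second moment so that Z = whitening %*% X
# holds exactly for the original X (used by IVA, whose output contract is
# y = W x on the stored window data).
whitenRows <- function(X, nc, center = TRUE) {
  if (center) X <- X - rowMeans(X)
  V <- ncol(X)
  C <- tcrossprod(X) / V
  e <- eigen(C, symmetric = TRUE)
  if (nc > sum(e$values > 1e-12 * e$values[1]))
    stop("requested whitening dimension exceeds numerical rank")
  d <- e$values[seq_len(nc)]
  E <- e$vectors[, seq_len(nc), drop = FALSE]
  Wh <- diag(1 / sqrt(d), nc) %*% t(E)
  Dw <- E %*% diag(sqrt(d), nc)
  list(Z = Wh %*% X, whitening = Wh, dewhitening = Dw)
}

# Random orthonormal n x n matrix from the current RNG stream.
randomOrthonormal <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}
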