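# Spatial dynamic FNC: normalized mutual information between SDC maps.
#
# Dependence between two spatial maps is measured by mutual information I
# estimated from an equal-frequency joint histogram with the Miller-Madow
# bias correction, then mapped to the information coefficient of correlation
# r* = sqrt(1 - exp(-2 I)), which lies in [0, 1), equals 0 exactly at
# independence, and equals |rho| for bivariate Gaussian inputs. Equal-
# frequency (rank-based) binning makes the estimate invariant to strictly
# monotone transforms of either map.

#' Map mutual information to the normalized [0, 1) scale
#'
#' The information coefficient of correlation \code{sqrt(1 - exp(-2 I))}:
#' 0 iff I = 0 (complete independence), approaching 1 as I grows, and equal to
#' |rho| when the inputs are bivariate Gaussian with correlation rho.
#'
#' @param I mutual information in nats (>= 0).
#' @return value(s) in [0, 1).
#' @export
miToR <- function(I) sqrt(1 - exp(-2 * pmax(I, 0)))

# Equal-frequency bin indices (1..nBins) for a numeric vector.
equalFreqBins <- function(x, nBins) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(nBins * r / (length(x) + 0.5))
  pmin(pmax(b, 1L), nBins)
}

#' Normalized mutual information between two spatial maps
#'
#' Estimates I from the joint histogram of equal-frequency bins (Miller-Madow
#' corrected, clamped at 0) and returns \code{miToR(I)}. Exactly symmetric in
#' its arguments.
#'
#' @param mapA,mapB numeric vectors of equal length V (non-constant).
#' @param nBins marginal bin count; default \code{max(8, floor(V^(1/3)))}.
#'   V must be at least \code{10 * nBins^2} for a stable estimate.
#' @return scalar in [0, 1).
#' @export
normalizedMI <- function(mapA, mapB, nBins = NULL) {
  V <- length(mapA)
  stopifnot(length(mapB) == V)
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0)
    stop("normalizedMI requires non-constant maps")
  if (is.null(nBins)) nBins <- max(8L, floor(V^(1 / 3)))
  nBins <- as.integer(nBins)
  if (V < 10 * nBins^2)
    stop(sprintf("V = %d too small for %d bins (need >= %d samples)",
                 V, nBins, 10 * nBins^2))
  ba <- equalFreqBins(mapA, nBins)
  bb <- equalFreqBins(mapB, nBins)
  joint <- table(factor(ba, levels = seq_len(nBins)),
                 factor(bb, levels = seq_len(nBins)))
  pj <- joint / V
  pa <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  I <- sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
  # Miller-Madow: I = Ha + Hb - Hab with H += (cells - 1)/(2V)
  mm <- (sum(pa > 0) - 1 + sum(pb > 0) - 1 - (sum(nz) - 1)) / (2 * V)
  miToR(max(I + mm, 0))
}

#' Normalized-MI connectivity between all SDC pairs
#'
#' For every (subject, window) dataset and every component pair (i < j), the
#' normalized MI between the two SDC maps. The diagonal is 0 by convention.
#'
#' @param scvset a (screened) \linkS4class{SCVSet}.
#' @param nBins marginal bin count (default as in [normalizedMI()]).
#' @return list with \code{values} (array M x L x P x P), \code{subjects},
#'   \code{windows}, \code{nBins}.
#' @export
miConnectivity <- function(scvset, nBins = NULL) {
  P <- scvset@nComponents
  idx <- scvset@datasetIndex
  M <- max(idx$subject)
  L <- max(idx$window)
  vals <- array(0, c(M, L, P, P))
  for (r in seq_len(nrow(idx))) {
    s <- scvset@sources[[r]]
    for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
      v <- normalizedMI(s[i, ], s[j, ], nBins = nBins)
      vals[idx$subject[r], idx$window[r], i, j] <- v
      vals[idx$subject[r], idx$window[r], j, i] <- v
    }
  }
  list(values = vals, subjects = seq_len(M), windows = seq_len(L),
       nBins = nBins)
}

#' Across-window variability of spatial connectivity
#'
#' Per subject and edge, the sample standard deviation (n - 1 denominator) of
#' the normalized MI across the L windows; optionally group-mean matrices.
#'
#' @param miStack result of [miConnectivity()].
#' @param groups optional per-subject group labels; when given, per-group mean
#'   STD matrices are added.
#' @return list with \code{stdPerSubject} (M x P x P array) and, when groups
#'   are supplied, \code{groupMeanStd} (named list of P x P matrices).
#' @export
edgeVariability <- function(miStack, groups = NULL) {
  vals <- miStack$values
  d <- dim(vals)
  M <- d[1]; L <- d[2]; P <- d[3]
  if (L < 2L) stop("need at least 2 windows to compute an STD")
  stdArr <- array(0, c(M, P, P))
  for (m in seq_len(M)) for (i in seq_len(P)) for (j in seq_len(P)) {
    if (i != j) stdArr[m, i, j] <- stats::sd(vals[m, , i, j])
  }
  out <- list(stdPerSubject = stdArr)
  if (!is.null(groups)) {
    stopifnot(length(groups) == M)
    out$groupMeanStd <- lapply(split(seq_len(M), groups), function(ms) {
      apply(stdArr[ms, , , drop = FALSE], c(2, 3), mean)
    })
  }
  out
}

#' Long-format export of an MI stack
#'
#' @param miStack result of [miConnectivity()].
#' @param subjectIds optional subject identifiers.
#' @return data.frame: subject_id, window, component_i, component_j, value
#'   (upper-triangle edges only).
#' @export
miLongFormat <- function(miStack, subjectIds = NULL) {
  d <- dim(miStack$values)
  if (is.null(subjectIds)) subjectIds <- sprintf("sub%02d", seq_len(d[1]))
  ep <- edgePairs(d[3])
  out <- do.call(rbind, lapply(seq_len(d[1]), function(m) {
    do.call(rbind, lapply(seq_len(d[2]), function(l) {
      data.frame(subject_id = subjectIds[m], window = l,
                 component_i = ep$i, component_j = ep$j,
                 value = miStack$values[m, l, , ][cbind(ep$i, ep$j)])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Heatmap of an edge matrix
#'
#' Minimal base-graphics heatmap for symmetric edge matrices (e.g. a group
#' mean STD matrix from [edgeVariability()]), with components on both axes.
#'
#' @param mat symmetric P x P numeric matrix.
#' @param main plot title.
#' @param zlim color range (default from the data).
#' @return invisibly, \code{mat}.
#' @export
plotEdgeMatrix <- function(mat, main = "", zlim = range(mat)) {
  P <- nrow(mat)
  graphics::image(seq_len(P), seq_len(P), t(mat[P:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = zlim, axes = FALSE, xlab = "component",
                  ylab = "component", main = main)
  graphics::axis(1, at = seq_len(P), labels = seq_len(P))
  graphics::axis(2, at = seq_len(P), labels = rev(seq_len(P)))
  graphics::box()
  invisible(mat)
}
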