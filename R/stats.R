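# Group comparison and clinical correlation.
#
# Edge-wise two-sample t-tests (pooled variance) compare groups on static and
# per-state dynamic FNC; the Mann-Whitney U test compares across-window STD of
# spatial connectivity; families of p-values are controlled by
# Benjamini-Hochberg FDR at alpha = 0.05; significant features are correlated
# with clinical scores by Pearson correlation.

#' Two-sample pooled-variance t-test
#'
#' Two-sided Student t-test (equal-variance pooling; set
#' \code{welch = TRUE} for the Welch variant).
#'
#' @param valuesA,valuesB numeric vectors (n >= 2 each, finite).
#' @param welch use the Welch unequal-variance test instead (default FALSE).
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
twoSampleT <- function(valuesA, valuesB, welch = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(valuesA)) || any(!is.finite(valuesB)))
    stop("non-finite values in input")
  ht <- stats::t.test(valuesA, valuesB, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined n <= 20 without ties the exact null
#' distribution is used; otherwise the normal approximation with tie
#' correction (and continuity correction). U is reported for the first
#' sample.
#'
#' @param valuesA,valuesB numeric vectors (n >= 1 each).
#' @param exact force the exact (TRUE) or approximate (FALSE) branch; NULL
#'   (default) selects automatically as described.
#' @return list with \code{U}, \code{p}, \code{exact} (logical).
#' @export
mannWhitneyU <- function(valuesA, valuesB, exact = NULL) {
  stopifnot(length(valuesA) >= 1L, length(valuesB) >= 1L)
  ties <- anyDuplicated(c(valuesA, valuesB)) > 0L
  if (is.null(exact))
    exact <- (length(valuesA) + length(valuesB)) <= 20L && !ties
  else if (isTRUE(exact) && ties)
    stop("exact branch is unavailable with ties")
  ht <- suppressWarnings(stats::wilcox.test(valuesA, valuesB, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure: q-values are \code{p * m / rank} made monotone by a
#' cumulative minimum; an edge is rejected iff its q-value is below
#' \code{alpha}.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{q} (q-values, same order as input) and
#'   \code{reject} (logical).
#' @export
fdrBH <- function(pValues, alpha = 0.05) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pValues, method = "BH")
  list(q = q, reject = q < alpha)
}

#' Group comparison of per-state dynamic FNC
#'
#' For each state, each subject's in-state windows are summarized by the
#' Fisher-z mean of the windowed correlations per edge; subjects with fewer
#' than \code{minWindows} windows of the state are excluded (membership
#' rule). Groups are compared edge-wise by [twoSampleT()] and corrected by
#' [fdrBH()] within the state (set \code{fdrFamily = "global"} to correct
#' across all states at once). States that retain fewer than 2 members in
#' either group are skipped with a recorded reason.
#'
#' @param stateModel a \linkS4class{StateModel}.
#' @param wfncList per-subject \linkS4class{WindowedFNC} list (same order as
#'   the model's assignments).
#' @param groups per-subject group labels (exactly 2 levels).
#' @param minWindows membership threshold (default 10).
#' @param alpha FDR level (default 0.05).
#' @param fdrFamily "state" (default) or "global".
#' @param welch passed to [twoSampleT()].
#' @return list with \code{results} (data.frame: state, component_i,
#'   component_j, t, p, q, significant, n_a, n_b), \code{skipped}
#'   (data.frame: state, reason), \code{groupLevels}.
#' @export
compareStateFNC <- function(stateModel, wfncList, groups, minWindows = 10L,
                            alpha = 0.05, fdrFamily = c("state", "global"),
                            welch = FALSE) {
  fdrFamily <- match.arg(fdrFamily)
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L, length(groups) == length(wfncList))
  asg <- stateModel@assignments
  stopifnot(length(asg) == length(wfncList))
  N <- dim(wfncList[[1]]@matrices)[2]
  ep <- edgePairs(N)
  rows <- list()
  skipped <- list()
  for (st in seq_len(stateModel@k)) {
    vals <- lapply(seq_along(wfncList), function(m) {
      w <- which(asg[[m]] == st)
      if (length(w) < minWindows) return(NULL)
      z <- windowVectors(wfncList[[m]])[w, , drop = FALSE]
      colMeans(z)
    })
    keep <- !vapply(vals, is.null, logical(1))
    nA <- sum(keep & groups == lv[1])
    nB <- sum(keep & groups == lv[2])
    if (nA < 2L || nB < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        state = st,
        reason = sprintf("only %d '%s' and %d '%s' members after the %d-window rule",
                         nA, lv[1], nB, lv[2], minWindows))
      next
    }
    A <- do.call(rbind, vals[keep & groups == lv[1]])
    B <- do.call(rbind, vals[keep & groups == lv[2]])
    tp <- vapply(seq_len(nrow(ep)), function(e) {
      ht <- twoSampleT(A[, e], B[, e], welch = welch)
      c(ht$t, ht$p)
    }, numeric(2))
    rows[[length(rows) + 1L]] <- data.frame(
      state = st, component_i = ep$i, component_j = ep$j,
      t = tp[1, ], p = tp[2, ], n_a = nA, n_b = nB)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = integer(), component_i = integer(),
               component_j = integer(), t = numeric(), p = numeric(),
               n_a = integer(), n_b = integer())
  if (nrow(res)) {
    if (fdrFamily == "state") {
      res$q <- NA_real_
      res$significant <- NA
      for (st in unique(res$state)) {
        sel <- res$state == st
        f <- fdrBH(res$p[sel], alpha)
        res$q[sel] <- f$q
        res$significant[sel] <- f$reject
      }
    } else {
      f <- fdrBH(res$p, alpha)
      res$q <- f$q
      res$significant <- f$reject
    }
  } else {
    res$q <- numeric(0)
    res$significant <- logical(0)
  }
  list(results = res[, c("state", "component_i", "component_j", "t", "p",
                         "q", "significant", "n_a", "n_b")],
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(state = integer(), reason = character()),
       groupLevels = lv)
}

#' Edge-wise group comparison of a per-subject feature matrix
#'
#' Generic helper for static FNC (t-test on Fisher-z correlations) or STD of
#' spatial connectivity (Mann-Whitney U): one test per column of
#' \code{features}, BH-corrected as one family.
#'
#' @param features M x E numeric matrix (subjects x edges).
#' @param groups per-subject labels (2 levels).
#' @param test "t" (pooled-variance t) or "u" (Mann-Whitney).
#' @param alpha FDR level.
#' @param edgeInfo optional data.frame with one row per column of
#'   \code{features} (e.g. component_i/component_j), prepended to the output.
#' @return data.frame with statistic, p, q, significant per edge.
#' @export
compareEdgeFeatures <- function(features, groups, test = c("t", "u"),
                                alpha = 0.05, edgeInfo = NULL) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L, nrow(features) == length(groups))
  a <- groups == lv[1]
  stat <- numeric(ncol(features))
  p <- numeric(ncol(features))
  for (e in seq_len(ncol(features))) {
    if (test == "t") {
      ht <- twoSampleT(features[a, e], features[!a, e])
      stat[e] <- ht$t
    } else {
      ht <- mannWhitneyU(features[a, e], features[!a, e])
      stat[e] <- ht$U
    }
    p[e] <- ht$p
  }
  f <- fdrBH(p, alpha)
  out <- data.frame(statistic = stat, p = p, q = f$q, significant = f$reject)
  if (!is.null(edgeInfo)) out <- cbind(edgeInfo, out)
  out
}

#' Pearson correlation between connectivity features and clinical scores
#'
#' Two-sided Pearson correlation per (feature, score) pair. Intended for
#' features already flagged significant by the group comparison.
#'
#' @param features named list (or data.frame) of per-subject feature vectors.
#' @param scores named list (or data.frame) of per-subject clinical scores.
#' @return data.frame: feature, score, r, p, n.
#' @export
correlateClinical <- function(features, scores) {
  features <- as.data.frame(features)
  scores <- as.data.frame(scores)
  stopifnot(nrow(features) == nrow(scores))
  out <- list()
  for (f in names(features)) for (s in names(scores)) {
    x <- features[[f]]; y <- scores[[s]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("need at least 3 paired finite observations")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop(sprintf("zero variance in '%s' or '%s'", f, s))
    ht <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out[[length(out) + 1L]] <- data.frame(
      feature = f, score = s, r = unname(ht$estimate), p = ht$p.value,
      n = sum(ok))
  }
  do.call(rbind, out)
}
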