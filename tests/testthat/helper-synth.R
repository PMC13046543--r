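# Shared fixtures and independent oracles used across test files.

# Unit-variance Laplacian sources, n x V.
laplacianSources <- function(n, V, seed = 1) {
  set.seed(seed)
  matrix(stats::rexp(n * V) * sample(c(-1, 1), n * V, TRUE), n, V) / sqrt(2)
}

# Majority-state label of each sliding window given a per-TR state sequence.
majorityWindowStates <- function(stateSeq, starts, width) {
  vapply(starts, function(s0) {
    seg <- stateSeq[(s0 + 1):(s0 + width)]
    as.integer(names(which.max(table(seg))))
  }, integer(1))
}

# Best label-permutation agreement between two label vectors (k small).
labelAccuracy <- function(est, truth, k) {
  perms <- dynetfnc:::permutationsAll(k)
  max(apply(perms, 1L, function(p) mean(p[est] == truth)))
}

# Enumeration oracle for the two-sided exact Mann-Whitney p-value.
mwEnumerationP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  uStat <- function(x, y) sum(outer(x, y, ">")) # U for first sample
  uObs <- uStat(a, b)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2L, function(ix) uStat(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# Brute-force Benjamini-Hochberg: largest k with p_(k) <= k * alpha / m.
bhBruteForce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  reject <- logical(m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Assemble an SCVSet directly from a list of per-dataset source-map matrices
# (used to test MI connectivity without running IVA).
scvSetFromMaps <- function(sourceList, M, L) {
  stopifnot(length(sourceList) == M * L)
  N <- nrow(sourceList[[1]])
  Tw <- 4L
  idx <- data.frame(dataset = seq_len(M * L),
                    subject = rep(seq_len(M), each = L),
                    window = rep(seq_len(L), times = M))
  demix <- lapply(seq_len(M * L), function(i) matrix(0, N, Tw))
  names(demix) <- names(sourceList) <-
    sprintf("m%02d_l%02d", idx$subject, idx$window)
  new("SCVSet", demixing = demix, sources = sourceList, datasetIndex = idx,
      nComponents = N, converged = c(ivaG = TRUE, ivaL = TRUE))
}

# StateModel built from known ground-truth window labels.
stateModelFromTruth <- function(assignments, k, E) {
  new("StateModel", k = as.integer(k), centroids = matrix(0, k, E),
      assignments = assignments,
      validityCurve = data.frame(k = integer(), score = numeric()))
}
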