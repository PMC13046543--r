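test_that("subject PCA is lossless at full rank and concatenation has M*npc rows", {
  set.seed(31)
  # rank-5 data: 20 x 50 built from 5 factors
  makeSeries <- function(id) {
    X <- matrix(rnorm(20 * 5), 20, 5) %*% matrix(rnorm(5 * 50), 5, 50)
    BoldSeries(X, maskIndices = 1:50, gridShape = c(50, 1, 1), subjectId = id)
  }
  series <- list(makeSeries("a"), makeSeries("b"))
  red <- reduceAndConcat(series, nSubjectPCs = 5, nGroupPCs = 10)
  expect_equal(nrow(red$groupData), 10L)
  # reconstruction residual is 0 when npc = rank
  X <- boldData(series[[1]])
  Xc <- X - matrix(colMeans(X), 20, 50, byrow = TRUE)
  U <- red$subjectOperators[[1]]
  expect_lt(max(abs(U %*% crossprod(U, Xc) - Xc)), 1e-8)
})

test_that("group PCA matches a direct eigendecomposition of the concatenated covariance", {
  set.seed(32)
  series <- lapply(1:2, function(m) {
    X <- matrix(rnorm(20 * 60), 20, 60)
    BoldSeries(X, maskIndices = 1:60, gridShape = c(60, 1, 1),
               subjectId = paste0("s", m))
  })
  red <- reduceAndConcat(series, nSubjectPCs = 6, nGroupPCs = 4)
  # oracle: brute-force eigendecomposition of the concatenated matrix
  concat <- do.call(rbind, lapply(series, function(s) {
    X <- boldData(s)
    Xc <- X - matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
    e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
    R <- crossprod(e$vectors[, 1:6], Xc)
    R / sqrt(mean(R^2))   # unit mean variance per subject, as documented
  }))
  eg <- eigen(tcrossprod(concat) / ncol(concat), symmetric = TRUE)
  for (k in 1:4) {
    cosine <- abs(sum(red$groupOperator[, k] * eg$vectors[, k]))
    expect_gt(cosine, 0.999)
  }
  expect_error(reduceAndConcat(series, nSubjectPCs = 6, nGroupPCs = 13),
               "concatenated")
})

test_that("extended Infomax separates noiseless non-Gaussian mixtures", {
  S <- laplacianSources(2, 5000, seed = 33)
  set.seed(34)
  A <- matrix(rnorm(4), 2, 2)
  res <- infomaxICA(A %*% S, 2, seed = 1)
  expect_true(res$converged)
  expect_lt(amariIndex(res$unmixing %*% A), 0.05)
  # identity mixing: gain is a permutation of identity up to tolerance
  res2 <- infomaxICA(S, 2, seed = 2)
  G <- abs(res2$unmixing)
  G <- G / apply(G, 1, max)
  offPeak <- apply(G, 1, function(r) sort(r, decreasing = TRUE)[2])
  expect_lt(max(offPeak), 0.25)
  expect_equal(sort(apply(G, 1, which.max)), 1:2)
})

test_that("Infomax solutions are stable across seeds", {
  S <- laplacianSources(3, 4000, seed = 35)
  set.seed(36)
  A <- matrix(rnorm(9), 3, 3)
  X <- A %*% S
  ra <- infomaxICA(X, 3, seed = 11)
  rb <- infomaxICA(X, 3, seed = 12)
  m <- matchComponents(ra$components, rb$components)
  expect_gt(min(abs(m$r)), 0.95)
})

test_that("ICASSO clusters stable components and flags unstable ones", {
  S <- laplacianSources(3, 3000, seed = 37)
  set.seed(38)
  A <- matrix(rnorm(9), 3, 3)
  X <- A %*% S
  # well-separated 3-source problem, 10 runs: full clusters, high iq
  ic <- icassoSelect(X, 3, nRuns = 10, minClusterSize = 8, seed = 40)
  expect_equal(ic$clusterInfo$size, rep(10L, 3))
  expect_true(all(ic$clusterInfo$iq > 0.9))
  expect_true(all(ic$clusterInfo$stable))
  m <- matchComponents(spatialMaps(ic$components), S)
  expect_gt(min(abs(m$r)), 0.95)
  # identical seeds reused: estimates coincide exactly, iq ~ 1
  ic2 <- icassoSelect(X, 3, nRuns = 5, minClusterSize = 5,
                      seeds = rep(7L, 5))
  expect_true(all(ic2$clusterInfo$iq > 0.9))
  expect_equal(ic2$clusterInfo$size, rep(5L, 3))
})

test_that("dual regression recovers maps and time courses exactly in the noiseless case", {
  src <- generateSpatialSources(c(10, 10, 10), 3, 1.5, seed = 41)
  S <- src$sources
  set.seed(42)
  TC <- matrix(rnorm(60 * 3), 60, 3)
  X <- TC %*% S
  series <- list(BoldSeries(X, maskIndices = src$maskIndices,
                            gridShape = c(10, 10, 10), subjectId = "s1"))
  subj <- backReconstruct(S, series = series)
  cs <- subj[[1]]
  # regression identity: reconstruction residual ~ 0
  tc <- cs@timeCourses[[1]]
  Xc <- X - matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  fit <- tc %*% solve(crossprod(tc), crossprod(tc, Xc))
  expect_lt(max(abs(fit - Xc)), 1e-8)
  # time courses match ground truth after matching
  cc <- abs(cor(tc, TC))
  expect_gt(min(apply(cc, 2, max)), 0.999)
  m <- matchComponents(spatialMaps(cs), S)
  expect_gt(min(abs(m$r)), 0.999)
})

test_that("the GICA chain is invariant to per-subject scalar rescaling", {
  ds <- generateDataset(nSubjects = 4, nTimepoints = 96, nSources = 3,
                        kStates = 2, snr = 10, spatialJitter = 0,
                        dwellMeanTrs = 30, ivaWindowTrs = 48, seed = 43)
  scaled <- lapply(seq_along(ds$series), function(m) {
    s <- ds$series[[m]]
    s@data <- s@data * c(0.1, 5, 40, 2)[m]
    s
  })
  run <- function(series) {
    red <- reduceAndConcat(series, 6, 3)
    icassoSelect(red$groupData, 3, nRuns = 4, minClusterSize = 3,
                 seed = 44)$components
  }
  m <- matchComponents(spatialMaps(run(scaled)),
                       spatialMaps(run(ds$series)))
  expect_equal(m$perm, 1:3)
  expect_gt(min(abs(m$r)), 0.999)
})

test_that("template labeling applies the artifact threshold and gray-matter rule", {
  src <- generateSpatialSources(c(10, 10, 10), 3, 1.5, seed = 45)
  templates <- src$sources
  rownames(templates) <- c("DMN", "SMN", "VIS")
  V <- ncol(templates)
  set.seed(46)
  noise <- rnorm(V)
  maps <- rbind(templates[2, ], (noise - mean(noise)) / sd(noise))
  cs <- ComponentSet(maps)
  lab <- labelComponents(cs, templates, artifactRThreshold = 0.2)
  expect_equal(componentLabels(lab), c("SMN", "artifact"))
  expect_equal(templateCorrelations(lab)$r[1], 1)
  expect_lt(templateCorrelations(lab)$r[2], 0.2)
  # gray-matter energy rule: a component concentrated outside gray matter
  gm <- rep(FALSE, V)
  gm[which(templates[1, ] > 0.5)] <- TRUE
  lab2 <- labelComponents(ComponentSet(rbind(templates[1, ], templates[3, ])),
                          templates, artifactRThreshold = 0.2,
                          grayMatterMask = gm)
  expect_equal(componentLabels(lab2)[2], "artifact")
  expect_error(labelComponents(cs, templates[0, , drop = FALSE]), "empty")
})

test_that("end-to-end GICA recovers the planted sources on clean synthetic data", {
  ds <- generateDataset(nSubjects = 6, nTimepoints = 192, nSources = 4,
                        kStates = 3, snr = 5, spatialJitter = 0, seed = 47)
  red <- reduceAndConcat(ds$series, 8, 4)
  ic <- icassoSelect(red$groupData, 4, nRuns = 8, minClusterSize = 6,
                     seed = 48)
  m <- matchComponents(spatialMaps(ic$components), spatialMaps(ds$truth))
  expect_gt(min(abs(m$r)), 0.9)
  subj <- backReconstruct(ic$components, red, ds$series)
  for (cs in subj[1:2]) {
    ms <- matchComponents(spatialMaps(cs), spatialMaps(ds$truth))
    expect_gt(min(abs(ms$r)), 0.8)
  }
  # sign convention: skewness of every group map is non-negative
  expect_true(all(rowMeans(spatialMaps(ic$components)^3) >= 0))
})
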