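mkSeries <- function(T, V, seed = 1, id = "s1") {
  set.seed(seed)
  BoldSeries(matrix(rnorm(T * V), T, V), maskIndices = seq_len(V),
             gridShape = c(V, 1, 1), subjectId = id)
}

test_that("window segmentation follows the stated arithmetic", {
  s <- mkSeries(192, 30, seed = 70)
  seg <- segmentWindows(s, windowTrs = 48, overlapFraction = 0.5)
  expect_equal(nWindows(seg), 7L)
  expect_equal(windowStarts(seg), seq(0L, 144L, by = 24L))
  # last window ends exactly at T
  expect_equal(windowStarts(seg)[7] + 48L, 192L)
  # window duration in seconds = windowTrs * TR
  expect_equal(48 * trSeconds(s), 96)
  # disjoint cover at zero overlap
  seg0 <- segmentWindows(s, windowTrs = 48, overlapFraction = 0)
  expect_equal(nWindows(seg0), 4L)
  expect_equal(windowStarts(seg0), c(0L, 48L, 96L, 144L))
  # invalid combinations are rejected with guidance
  expect_error(segmentWindows(mkSeries(190, 30, seed = 71), 48, 0.5),
               "divisible")
  expect_error(segmentWindows(s, 48, 0.3), "integer")
})

test_that("window content is the demeaned series block", {
  s <- mkSeries(96, 20, seed = 72)
  seg <- segmentWindows(s, windowTrs = 48, overlapFraction = 0.5)
  block <- boldData(s)[25:72, ]
  expect_equal(seg@windows[[2]],
               block - matrix(colMeans(block), 48, 20, byrow = TRUE))
  segV <- segmentWindows(s, 48, 0.5, normalize = "voxel")
  expect_equal(apply(segV@windows[[2]], 2, sd), rep(1, 20))
})

ivaTestProblem <- function(K, N, V, rho, seed, laplacian = FALSE) {
  set.seed(seed)
  scv <- lapply(seq_len(N), function(n) {
    C <- matrix(rho[n], K, K); diag(C) <- 1
    Z <- if (laplacian)
      matrix(rexp(K * V) * sample(c(-1, 1), K * V, TRUE), K, V) / sqrt(2)
    else matrix(rnorm(K * V), K, V)
    t(chol(C)) %*% Z
  })
  S <- lapply(seq_len(K), function(k)
    do.call(rbind, lapply(scv, function(s) s[k, ])))
  A <- lapply(seq_len(K), function(k) matrix(rnorm(N * N), N, N))
  X <- lapply(seq_len(K), function(k) A[[k]] %*% S[[k]])
  list(X = X, A = A, S = S)
}

test_that("IVA-G separates SCVs with distinct cross-dataset covariance", {
  pr <- ivaTestProblem(K = 4, N = 3, V = 3000, rho = c(0.95, 0.7, 0.4),
                       seed = 73)
  g <- ivaG(pr$X, 3, seed = 1)
  expect_true(g$converged)
  gains <- lapply(1:4, function(k) g$demixing[[k]] %*% pr$A[[k]])
  expect_lt(jointISI(gains), 0.1)
  # permutation consistency: component n matches source n in every dataset
  # after one global matching
  perDataset <- vapply(gains, function(G) {
    all(apply(abs(G), 1, which.max) == apply(abs(gains[[1]]), 1, which.max))
  }, logical(1))
  expect_gt(mean(perDataset), 0.95)
})

test_that("identical datasets yield near-perfectly correlated SCV members", {
  set.seed(74)
  S <- laplacianSources(3, 2000, seed = 74)
  A <- matrix(rnorm(9), 3, 3)
  X <- A %*% S
  # the duplicated-dataset cost is degenerate (singular SCV covariance), so
  # the gradient tolerance is never met; the separation itself is exact
  g <- suppressWarnings(ivaG(list(X, X), 3, seed = 2))
  for (n in 1:3) {
    y1 <- g$sources[[1]][n, ]
    y2 <- g$sources[[2]][n, ]
    expect_gt(abs(cor(y1, y2)), 0.99)
  }
})

test_that("IVA-L separates sparse sources and profits from a warm start", {
  pr <- ivaTestProblem(K = 3, N = 3, V = 3000, rho = c(0.9, 0.9, 0.9),
                       seed = 75, laplacian = TRUE)
  l <- ivaL(pr$X, 3, seed = 3)
  gains <- lapply(1:3, function(k) l$demixing[[k]] %*% pr$A[[k]])
  expect_lt(jointISI(gains), 0.1)
  # warm start at the converged solution returns almost immediately
  l2 <- ivaL(pr$X, 3, initDemixing = l$W, seed = 4)
  expect_lt(l2$iterations, 20)
  gains2 <- lapply(1:3, function(k) l2$demixing[[k]] %*% pr$A[[k]])
  expect_lt(jointISI(gains2), 0.02)
})

test_that("IVA-L initialized from IVA-G is no worse on Gaussian sources", {
  pr <- ivaTestProblem(K = 3, N = 3, V = 3000, rho = c(0.95, 0.7, 0.4),
                       seed = 76)
  g <- ivaG(pr$X, 3, seed = 5)
  isiG <- jointISI(lapply(1:3, function(k) g$demixing[[k]] %*% pr$A[[k]]))
  l <- suppressWarnings(ivaL(pr$X, 3, initDemixing = g$W, maxIter = 256))
  isiL <- jointISI(lapply(1:3, function(k) l$demixing[[k]] %*% pr$A[[k]]))
  expect_lt(isiL, isiG + 0.05)
})

test_that("IVA-GL on jitter-free noiseless data gives near-identical maps across windows", {
  ds <- generateDataset(nSubjects = 4, nTimepoints = 192,
                        gridShape = c(12, 12, 12), nSources = 3, kStates = 2,
                        snr = Inf, spatialJitter = 0, seed = 77)
  segs <- lapply(ds$series, segmentWindows)
  scv <- suppressWarnings(ivaGL(segs, nComponents = 3, seed = 6,
                                maxIter = 512))
  expect_equal(length(scvSources(scv)), 4L * 7L)
  for (n in 1:3) {
    stack <- scvMatrix(scv, n)
    R <- abs(cor(t(stack)))
    expect_gt(min(R[upper.tri(R)]), 0.95)
  }
})

test_that("the SCVSet is organized by (subject, window) with aligned components", {
  ds <- generateDataset(nSubjects = 2, nTimepoints = 96,
                        gridShape = c(10, 10, 10), nSources = 2, kStates = 1,
                        snr = 10, spatialJitter = 0, dwellMeanTrs = 40,
                        ivaWindowTrs = 48, seed = 78)
  segs <- lapply(ds$series, segmentWindows, windowTrs = 48)
  scv <- suppressWarnings(ivaGL(segs, nComponents = 2, seed = 7,
                                maxIter = 128))
  idx <- datasetIndex(scv)
  expect_equal(nrow(idx), 2L * 3L)
  expect_equal(idx$subject, rep(1:2, each = 3))
  expect_equal(idx$window, rep(1:3, times = 2))
  # y = W x exactly, with W including the whitening
  r <- 4L
  x <- segs[[idx$subject[r]]]@windows[[idx$window[r]]]
  expect_lt(max(abs(scvSources(scv)[[r]] - scvDemixing(scv)[[r]] %*% x)),
            1e-10)
  # every SCV collects one row from every dataset
  expect_equal(dim(scvMatrix(scv, 1)), c(6L, ncol(boldData(ds$series[[1]]))))
})

test_that("SDC screening keeps planted components and is the identity at full keep", {
  src <- generateSpatialSources(c(12, 12, 12), 4, 2, seed = 79)
  real <- src$sources
  set.seed(80)
  V <- ncol(real)
  mkMaps <- function() {
    noise <- matrix(rnorm(2 * V), 2, V)
    rbind(real + matrix(rnorm(4 * V, sd = 0.1), 4, V), noise)
  }
  sources <- lapply(1:6, function(i) mkMaps())
  scv <- scvSetFromMaps(sources, M = 2, L = 3)
  scr <- screenSDCs(scv, real, keep = 4)
  expect_equal(scr$kept, 1:4)
  expect_equal(nComponents(scr$scvset), 4L)
  full <- screenSDCs(scv, real, keep = 6)
  expect_equal(full$kept, 1:6)
  expect_equal(scvSources(full$scvset), scvSources(scv))
})
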