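test_that("spatial sources are separated, z-scaled, and seed-deterministic", {
  src <- generateSpatialSources(c(12, 12, 12), 4, 2, seed = 1)
  expect_equal(dim(src$sources), c(4L, length(src$maskIndices)))
  R <- cor(t(src$sources))
  diag(R) <- 0
  expect_lt(max(abs(R)), 0.2)
  expect_equal(rowMeans(src$sources), rep(0, 4))
  expect_equal(apply(src$sources, 1, sd), rep(1, 4))
  expect_identical(src, generateSpatialSources(c(12, 12, 12), 4, 2, seed = 1))
  expect_false(identical(src$sources,
                         generateSpatialSources(c(12, 12, 12), 4, 2,
                                                seed = 2)$sources))
})

test_that("source placement fails explicitly on a grid that is too small", {
  expect_error(generateSpatialSources(c(4, 4, 4), 50, 2, seed = 1),
               "placement failure")
})

test_that("state time courses match their covariance model", {
  # single state, identity covariance: off-diagonal correlations near 0
  st <- generateStateTimecourses(2000, list(diag(4)), dwellMeanTrs = 2000,
                                 seed = 1)
  expect_equal(length(unique(st$stateSequence)), 1L)
  R <- cor(st$timeCourses)
  diag(R) <- 0
  expect_lt(max(abs(R)), 4.5 / sqrt(2000))  # conservative bound over 6 pairs

  # two distinct states at T = 192: both labels occur
  C1 <- diag(3)
  C2 <- matrix(0.7, 3, 3); diag(C2) <- 1
  st2 <- generateStateTimecourses(192, list(C1, C2), dwellMeanTrs = 40,
                                  seed = 2)
  expect_setequal(unique(st2$stateSequence), 1:2)
  expect_equal(length(st2$stateSequence), 192L)

  # within-state empirical covariance converges to the generating one
  st3 <- generateStateTimecourses(5000, list(C1, C2), dwellMeanTrs = 500,
                                  seed = 3)
  rows2 <- st3$stateSequence == 2L
  expect_gt(sum(rows2), 500)
  emp <- cor(st3$timeCourses[rows2, ])
  expect_lt(max(abs(emp - C2)), 0.1)
})

test_that("non-positive-definite covariance is rejected", {
  bad <- matrix(1, 3, 3)
  expect_error(generateStateTimecourses(100, list(bad), 10, seed = 1),
               "positive definite")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(generateStateTimecourses(100, list(asym), 10, seed = 1),
               "symmetric")
})

test_that("noiseless jitter-free data equal timecourses times sources exactly", {
  ds <- generateDataset(nSubjects = 2, nTimepoints = 96,
                        gridShape = c(10, 10, 10), nSources = 3, kStates = 2,
                        snr = Inf, spatialJitter = 0, dwellMeanTrs = 30,
                        ivaWindowTrs = 48, seed = 4)
  S <- spatialMaps(ds$truth)
  for (m in 1:2) {
    recon <- timeCourses(ds$truth)[[m]] %*% S
    expect_lt(max(abs(boldData(ds$series[[m]]) - recon)), 1e-12)
  }
})

test_that("study-scale generation yields 24 subjects with 192 time points", {
  ds <- generateDataset(nSubjects = 24, nTimepoints = 192,
                        gridShape = c(10, 10, 10), nSources = 3,
                        snr = Inf, spatialJitter = 0, seed = 5)
  expect_length(ds$series, 24L)
  for (s in ds$series) expect_equal(nrow(boldData(s)), 192L)
  clin <- clinicalTable(ds$truth)
  expect_equal(sum(clin$group == "TS"), 12L)
  expect_equal(sum(clin$group == "N"), 12L)
  expect_true(all(clin$score >= 10 & clin$score <= 79))
  expect_true(all(clin$duration_months[clin$group == "TS"] >= 1 &
                    clin$duration_months[clin$group == "TS"] <= 12))
})

test_that("generation is bit-identical under a repeated seed", {
  a <- generateDataset(nSubjects = 2, nTimepoints = 96,
                       gridShape = c(10, 10, 10), nSources = 3, snr = 5,
                       spatialJitter = 0.1, dwellMeanTrs = 40,
                       ivaWindowTrs = 48, seed = 7)
  b <- generateDataset(nSubjects = 2, nTimepoints = 96,
                       gridShape = c(10, 10, 10), nSources = 3, snr = 5,
                       spatialJitter = 0.1, dwellMeanTrs = 40,
                       ivaWindowTrs = 48, seed = 7)
  expect_identical(boldData(a$series[[1]]), boldData(b$series[[1]]))
  expect_identical(clinicalTable(a$truth), clinicalTable(b$truth))
})

test_that("the realized signal-to-noise ratio honors the request", {
  snr <- 5
  ds <- generateDataset(nSubjects = 2, nTimepoints = 192, nSources = 4,
                        snr = snr, spatialJitter = 0, seed = 8)
  for (m in 1:2) {
    signal <- timeCourses(ds$truth)[[m]] %*% spatialMaps(ds$truth)
    noise <- boldData(ds$series[[m]]) - signal
    ratio <- var(as.vector(signal)) / var(as.vector(noise))
    expect_lt(abs(ratio - snr) / snr, 0.1)
  }
})

test_that("planted-effect specifications are validated", {
  expect_error(generateDataset(nSubjects = 2, nTimepoints = 96,
                               gridShape = c(10, 10, 10), nSources = 3,
                               plantedEffects = list(
                                 groupDeltaR = list(state = 1,
                                                    edge = c(1, 7),
                                                    delta = 0.3)),
                               seed = 1),
               "source index")
  expect_error(generateDataset(nSubjects = 2, nTimepoints = 96,
                               gridShape = c(10, 10, 10), nSources = 3,
                               kStates = 2,
                               plantedEffects = list(
                                 clinicalR = list(state = 5, edge = c(1, 2),
                                                  r = 0.5)),
                               seed = 1),
               "state")
})

test_that("a planted clinical correlation is recovered from the ground truth", {
  # noiseless, no jitter: cor(score, true edge strength) ~ requested r
  rs <- vapply(1:20, function(rep) {
    ds <- generateDataset(nSubjects = 24, nTimepoints = 96,
                          gridShape = c(8, 8, 8), nSources = 4, kStates = 1,
                          snr = Inf, spatialJitter = 0, blobRadiusVox = 1.2,
                          dwellMeanTrs = 40,
                          plantedEffects = list(
                            clinicalR = list(edge = c(1, 3), r = 0.7,
                                             sd = 0.15)),
                          seed = 4000 + rep)
    cor(clinicalTable(ds$truth)$score,
        ds$truth@genParams$realizedClinicalEdge)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.15)
})
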