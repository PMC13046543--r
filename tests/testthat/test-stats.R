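test_that("the pooled t-test matches its closed form and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # closed-form oracle: pooled s^2 = 1, se = sqrt(2/3), df = 4
  tOracle <- (mean(a) - mean(b)) / sqrt(1 * (1 / 3 + 1 / 3))
  pOracle <- 2 * pt(tOracle, df = 4)
  ht <- twoSampleT(a, b)
  expect_equal(ht$t, tOracle)
  expect_equal(ht$p, pOracle)
  expect_equal(ht$df, 4)
  sw <- twoSampleT(b, a)
  expect_equal(sw$t, -ht$t)
  expect_equal(sw$p, ht$p)
  # identical groups: t = 0, p = 1
  id <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
  expect_error(twoSampleT(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("Mann-Whitney agrees with rank-arrangement enumeration", {
  ht <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(unname(ht$U), 0)
  expect_true(ht$exact)
  expect_equal(ht$p, 1 / 3)
  expect_equal(ht$p, mwEnumerationP(c(1, 2), c(3, 4)))
  # exhaustive agreement for all splits of distinct values, combined n <= 8
  for (n in 4:8) {
    vals <- seq_len(n) + 0.5
    for (na in 2:(n - 2)) {
      sets <- utils::combn(n, na)
      for (j in seq_len(min(ncol(sets), 12))) {
        a <- vals[sets[, j]]; b <- vals[-sets[, j]]
        expect_equal(mannWhitneyU(a, b)$p, mwEnumerationP(a, b))
      }
    }
  }
})

test_that("Mann-Whitney tie handling and branch agreement behave as documented", {
  # identical multisets: U = n^2/2, p = 1 under the tie-corrected normal branch
  ht <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ht$U), 4.5)
  expect_false(ht$exact)
  expect_equal(ht$p, 1)
  # exact and approximate branches agree closely at n = 10 vs 10
  set.seed(101)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10, mean = 0.5)
    pe <- mannWhitneyU(a, b, exact = TRUE)$p
    pa <- mannWhitneyU(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(mannWhitneyU(c(1, 1), c(2, 3), exact = TRUE), "ties")
})

test_that("BH correction matches hand computation and the brute-force rule", {
  f <- fdrBH(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_equal(f$q, c(0.03, 0.03, 0.03))
  expect_true(all(f$reject))
  expect_equal(fdrBH(0.04)$q, 0.04)
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute force: largest k with p_(k) <= k alpha / m
  set.seed(102)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdrBH(p, 0.05)$reject, bhBruteForce(p, 0.05))
  }
  # q-values dominate raw p-values
  p <- runif(50)
  expect_true(all(fdrBH(p)$q >= p))
})

test_that("per-state group comparison applies the membership rule and skips thin states", {
  covs <- dynetfnc:::defaultStateCovariances(3, 2)
  wfnc <- list(); asg <- list()
  groups <- rep(c("TS", "N"), each = 3)
  for (m in 1:6) {
    st <- generateStateTimecourses(192, covs, 40, seed = 120 + m)
    wfnc[[m]] <- slidingWindowFNC(st$timeCourses, 18, 1)
    asg[[m]] <- majorityWindowStates(st$stateSequence,
                                     windowStarts(wfnc[[m]]), 18)
  }
  sm <- stateModelFromTruth(asg, k = 2, E = 3)
  res <- compareStateFNC(sm, wfnc, groups, minWindows = 10)
  expect_true(all(res$results$q >= res$results$p))
  expect_equal(res$results$significant, res$results$q < 0.05)
  # a state visited by almost nobody is skipped with a reason
  asg2 <- lapply(asg, function(a) { a[a == 2] <- 1L; a })
  asg2[[1]][1:20] <- 2L
  sm2 <- stateModelFromTruth(asg2, k = 2, E = 3)
  res2 <- compareStateFNC(sm2, wfnc, groups, minWindows = 10)
  expect_equal(res2$skipped$state, 2L)
  expect_false(2L %in% res2$results$state)
})

test_that("a planted group difference is detected in the right state and edge", {
  ds <- generateDataset(nSubjects = 24, nTimepoints = 192,
                        gridShape = c(8, 8, 8), nSources = 4, kStates = 3,
                        snr = Inf, spatialJitter = 0, blobRadiusVox = 1.2,
                        plantedEffects = list(
                          groupDeltaR = list(state = 2, edge = c(1, 2),
                                             delta = 0.5)),
                        seed = 130)
  wfnc <- lapply(timeCourses(ds$truth), slidingWindowFNC,
                 widthTrs = 18, stepTrs = 1)
  asg <- lapply(seq_along(wfnc), function(m)
    majorityWindowStates(stateSequences(ds$truth)[[m]],
                         windowStarts(wfnc[[m]]), 18))
  sm <- stateModelFromTruth(asg, k = 3, E = 6)
  res <- compareStateFNC(sm, wfnc, clinicalTable(ds$truth)$group,
                         minWindows = 10)$results
  hit <- res[res$state == 2 & res$component_i == 1 & res$component_j == 2, ]
  expect_true(hit$significant)
  # the TS group has the higher correlation on the planted edge
  expect_gt(hit$t, 0)
})

test_that("clinical correlation is exact on deterministic input and calibrated under the null", {
  score <- c(3, 1, 4, 1, 5, 9, 2, 6)
  feat <- 2 * score + 1
  cc <- correlateClinical(list(f = feat), list(s = score))
  expect_equal(cc$r, 1)
  expect_equal(cc$n, 8)
  expect_error(correlateClinical(list(f = rep(1, 5)), list(s = 1:5)),
               "zero variance")
  # permutation-style null at n = 12: rejection rate ~ alpha
  set.seed(103)
  rej <- vapply(1:400, function(i) {
    correlateClinical(list(f = rnorm(12)), list(s = rnorm(12)))$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})
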