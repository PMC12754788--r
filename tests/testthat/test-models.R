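test_that("linear fit recovers a noiseless slope and flags bad designs", {
  set.seed(31)
  g <- rbinom(300, 2, 0.3)
  fr <- fitLinear(0.3 * g, g)
  expect_equal(effectEstimate(fr), 0.3, tolerance = 1e-10)
  expect_lt(pValue(fr), 1e-200)
  # monomorphic / near-monomorphic: skipped, not an error
  gmono <- c(1, rep(0, 99))
  sk <- fitLinear(rnorm(100), gmono)
  expect_false(isConverged(sk))
  expect_true(is.na(effectEstimate(sk)))
  expect_match(sk@diagnostics$reason, "allele count")
  # rank-deficient design errors
  expect_error(fitLinear(rnorm(300), g, covariates = cbind(g)),
               "rank-deficient")
})

test_that("tobit equals OLS in the uncensored limit", {
  for (s in 1:10) {
    d <- makeCensored(1000, 0.1, 0.3, 0, seed = 300 + s)
    lin <- fitLinear(prepareLinearOutcome(d$ph), d$g)
    tob <- fitTobit(prepareTobitOutcome(d$ph), d$g)
    expect_lt(abs(effectEstimate(lin) - effectEstimate(tob)), 1e-6)
    # same beta and se; p differs only through the t vs normal
    # reference, which agrees on the log scale
    expect_lt(abs(standardError(lin) - standardError(tob)), 1e-10)
    expect_lt(abs(log(pValue(lin)) - log(pValue(tob))) /
                abs(log(pValue(lin))), 0.02)
    expect_true(isConverged(tob))
  }
})

test_that("tobit matches the brute-force likelihood oracle", {
  d <- makeCensored(50, 0.4, 0.3, 0.4, seed = 32)
  to <- prepareTobitOutcome(d$ph)
  fr <- fitTobit(to, d$g)
  oracle <- tobitGridOracle(transformedValues(to), d$g,
                            censorThreshold(to))
  expect_true(isConverged(fr))
  expect_lt(abs(effectEstimate(fr) - oracle$b1), 1e-4)
  expect_lt(abs(fr@sigma - oracle$sigma), 1e-4)
  # second fixture, heavier censoring
  d2 <- makeCensored(60, -0.3, 0.2, 0.6, seed = 33)
  to2 <- prepareTobitOutcome(d2$ph)
  fr2 <- fitTobit(to2, d2$g)
  oracle2 <- tobitGridOracle(transformedValues(to2), d2$g,
                             censorThreshold(to2))
  expect_lt(abs(effectEstimate(fr2) - oracle2$b1), 1e-4)
})

test_that("tobit handles covariates and refuses all-censored input", {
  set.seed(34)
  g <- rbinom(800, 2, 0.3)
  x <- rnorm(800)
  y <- 0.2 * g + 0.5 * x + rnorm(800)
  ph <- applyCensoring(y, 0.4)
  fr <- fitTobit(prepareTobitOutcome(ph), g, covariates = cbind(age = x))
  expect_true(isConverged(fr))
  expect_lt(abs(effectEstimate(fr) - 0.2), 4 * standardError(fr))
  to <- prepareTobitOutcome(ph)
  bad <- methods::new("TransformedOutcome",
                      values = transformedValues(to), tiesPolicy = "max",
                      offset = 3 / 8,
                      censorThreshold = max(transformedValues(to)) + 1)
  expect_error(fitTobit(bad, g), "all observations censored")
})

test_that("cox fit matches the hand-computed partial likelihood", {
  # 6 observations, distinct event times, censored block at the end
  ph <- CensoredPhenotype(c(1, 1, 2.5, 3.5, 5, 9), lod = 1)
  g <- c(0, 1, 2, 0, 1, 2)
  co <- prepareCoxOutcome(ph)
  fr <- fitCox(co, g)
  oracle <- coxOracle(pseudoTime(co), eventIndicator(co), g)
  expect_lt(abs(effectEstimate(fr) - oracle), 1e-6)
  expect_error(fitCox(co, g, covariates = cbind(g)), "rank-deficient")
  allCens <- methods::new("CoxOutcome", pseudoTime = c(1, 1, 0),
                          event = rep(FALSE, 3))
  expect_error(fitCox(allCens, c(0, 1, 2)), "no events")
})

test_that("schoenfeld test flags genotype-driven PH violations and stays
           calibrated under permutation", {
  set.seed(35)
  viol <- 0
  for (r in 1:30) {
    d <- makeCensored(4000, 0.25, 0.3, 0.3, seed = 3500 + r)
    fr <- fitCox(prepareCoxOutcome(d$ph), d$g)
    if (schoenfeldPHTest(fr) < 0.05) viol <- viol + 1
  }
  expect_gt(viol, 15)  # majority of replicates
  # permuted genotype: null p-values roughly uniform
  pnull <- vapply(1:60, function(r) {
    d <- makeCensored(1500, 0.25, 0.3, 0.3, seed = 36000 + r)
    gperm <- sample(d$g)
    schoenfeldPHTest(fitCox(prepareCoxOutcome(d$ph), gperm))
  }, numeric(1))
  expect_gt(ks.test(pnull, "punif")$p.value, 0.01)
  # transform choice is exposed
  d <- makeCensored(500, 0.2, 0.3, 0.3, seed = 37)
  fr <- fitCox(prepareCoxOutcome(d$ph), d$g)
  expect_false(identical(schoenfeldPHTest(fr, "km"),
                         schoenfeldPHTest(fr, "identity")))
})

test_that("logistic fit matches the 2x2 closed form and guards degeneracy", {
  g <- rep(c(0, 1), c(30, 30))
  ev <- c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(20, 10)))
  fr <- fitLogistic(ev, g)
  expect_equal(effectEstimate(fr), log(4), tolerance = 1e-6)
  expect_true(isConverged(fr))
  expect_error(fitLogistic(rep(TRUE, 50), rbinom(50, 2, 0.3)),
               "single-class")
  small <- fitLogistic(c(rep(TRUE, 55), rep(FALSE, 5)),
                       rbinom(60, 2, 0.3))
  expect_false(isConverged(small))
  expect_match(small@diagnostics$reason, "minority")
})

test_that("all four models hold the nominal type-I error rate", {
  nRep <- 200
  pmat <- matrix(NA_real_, nRep, 4,
                 dimnames = list(NULL, c("linear", "tobit", "cox",
                                         "logistic")))
  for (r in 1:nRep) {
    d <- makeCensored(800, 0, 0.3, 0.4, seed = 38000 + r)
    pmat[r, "linear"] <- pValue(fitLinear(prepareLinearOutcome(d$ph),
                                          d$g))
    pmat[r, "tobit"] <- pValue(fitTobit(prepareTobitOutcome(d$ph), d$g))
    pmat[r, "cox"] <- pValue(fitCox(prepareCoxOutcome(d$ph), d$g))
    pmat[r, "logistic"] <- pValue(fitLogistic(
      prepareLogisticOutcome(d$ph), d$g))
  }
  fpr <- colMeans(pmat < 0.05)
  # Binomial(200, 0.05): allow +/- 4 sd around the nominal level
  for (m in colnames(pmat)) {
    expect_gt(fpr[[m]], 0.05 - 4 * sqrt(0.05 * 0.95 / nRep))
    expect_lt(fpr[[m]], 0.05 + 4 * sqrt(0.05 * 0.95 / nRep))
  }
})

test_that("linear attenuates more than tobit under censoring", {
  est <- vapply(1:60, function(r) {
    d <- makeCensored(2000, 0.1, 0.3, 0.5, seed = 3900 + r)
    c(effectEstimate(fitLinear(prepareLinearOutcome(d$ph), d$g)),
      effectEstimate(fitTobit(prepareTobitOutcome(d$ph), d$g)))
  }, numeric(2))
  expect_lt(mean(est[1, ]), mean(est[2, ]))
  expect_lt(mean(est[1, ]), 0.1)  # systematic underestimation
})
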