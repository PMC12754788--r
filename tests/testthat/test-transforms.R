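test_that("rank-INT reproduces the closed-form Blom quantiles", {
  to <- rankInverseNormal(c(1, 2, 3))
  expect_equal(transformedValues(to),
               qnorm(c(0.625, 1.625, 2.625) / 3.25))
  expect_equal(transformedValues(to)[2], 0)  # middle rank at the median
  # tied pair under both policies on [c, c, 5, 9]
  mx <- rankInverseNormal(c(1, 1, 5, 9), "max")
  av <- rankInverseNormal(c(1, 1, 5, 9), "average")
  expect_equal(transformedValues(mx)[1:2],
               rep(qnorm((2 - 0.375) / 4.25), 2))
  expect_equal(transformedValues(av)[1:2],
               rep(qnorm((1.5 - 0.375) / 4.25), 2))
  expect_error(rankInverseNormal(rep(2, 5)), "identical")
  expect_error(rankInverseNormal(3), "at least 2")
})

test_that("rank-INT without ties is a standardized monotone transform", {
  set.seed(21)
  for (n in c(50, 500)) {
    x <- rnorm(n)
    v <- transformedValues(rankInverseNormal(x))
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_lt(abs(var(v) - 1), 0.06)
    expect_equal(cor(x, v, method = "spearman"), 1)
    # policies coincide exactly when there are no ties
    expect_identical(v, transformedValues(rankInverseNormal(x, "max")))
  }
})

test_that("linear preparation imputes the censored block at the average rank", {
  d <- makeCensored(1000, 0, 0.2, 0.5, seed = 22)
  to <- prepareLinearOutcome(d$ph)
  cen <- isCensored(d$ph)
  expect_equal(length(unique(transformedValues(to)[cen])), 1L)
  expect_lt(transformedValues(to)[cen][1], 0)  # lower half maps below 0
  expect_length(censorThreshold(to), 0)
  # toy: censored pair of 4 at the average-rank quantile
  ph4 <- CensoredPhenotype(c(1, 1, 5, 9), lod = 1)
  expect_equal(transformedValues(prepareLinearOutcome(ph4))[1],
               qnorm(1.125 / 4.25))
  # no censoring: identical to plain rank-INT
  d0 <- makeCensored(100, 0, 0.2, 0, seed = 23)
  expect_identical(
    transformedValues(prepareLinearOutcome(d0$ph)),
    transformedValues(rankInverseNormal(observedValues(d0$ph))))
})

test_that("tobit preparation places the censored block at the threshold", {
  ph4 <- CensoredPhenotype(c(1, 1, 5, 9), lod = 1)
  to <- prepareTobitOutcome(ph4)
  expect_equal(censorThreshold(to), qnorm(1.625 / 4.25))
  expect_equal(transformedValues(to)[1:2],
               rep(censorThreshold(to), 2))
  # 90% censored, n = 1000: threshold at the max-tie rank 900
  d <- makeCensored(1000, 0, 0.2, 0.9, seed = 24)
  to9 <- prepareTobitOutcome(d$ph)
  expect_equal(censorThreshold(to9), qnorm((900 - 0.375) / 1000.25))
  # uncensored: threshold strictly below every value
  d0 <- makeCensored(100, 0, 0.2, 0, seed = 25)
  to0 <- prepareTobitOutcome(d0$ph)
  expect_lt(censorThreshold(to0), min(transformedValues(to0)))
  # average policy imputes strictly below the max-policy value
  expect_lt(transformedValues(prepareLinearOutcome(ph4))[1],
            transformedValues(prepareTobitOutcome(ph4))[1])
})

test_that("Cox flip reverses the scale and marks detections as events", {
  ph <- CensoredPhenotype(c(1, 2, 5), lod = 1)
  co <- prepareCoxOutcome(ph)
  expect_equal(pseudoTime(co), c(4, 3, 0))
  expect_identical(eventIndicator(co), c(FALSE, TRUE, TRUE))
  expect_equal(min(pseudoTime(co)), 0)
  # ordering is exactly reversed on distinct values
  d <- makeCensored(200, 0, 0.3, 0, seed = 26)
  co2 <- prepareCoxOutcome(d$ph)
  expect_true(all(eventIndicator(co2)))
  expect_equal(cor(pseudoTime(co2), observedValues(d$ph),
                   method = "kendall"), -1)
})

test_that("logistic indicator is the detection status", {
  ph <- CensoredPhenotype(c(1, 1, 5), lod = 1)
  expect_identical(prepareLogisticOutcome(ph), c(FALSE, FALSE, TRUE))
  d <- makeCensored(2000, 0, 0.2, 0.3, seed = 27)
  delta <- prepareLogisticOutcome(d$ph)
  expect_lt(abs(mean(delta) - 0.7), 1 / 2000 + 1e-12)
  d0 <- makeCensored(100, 0, 0.2, 0, seed = 28)
  expect_error(prepareLogisticOutcome(d0$ph), "single-class")
})
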