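test_that("detection rate counts significant replicates", {
  expect_equal(detectionRate(c(1e-9, 0.2, 3e-8), 5e-8), 2 / 3)
  expect_equal(detectionRate(c(0.1, 0.5), 1), 1)
  expect_equal(detectionRate(c(0.1, NA, 0.5), 0.2), 1 / 3)
  expect_error(detectionRate(numeric(0), 0.05), "empty")
  expect_error(detectionRate(c(0.5, 1.2), 0.05), "p-values")
})

test_that("Wald CI for an empirical rate matches the closed form", {
  ci <- fprWaldCI(0.05, 1000)
  expect_equal(unname(round(ci, 4)), c(0.0365, 0.0635))
  expect_equal(unname(fprWaldCI(0.05, 1000, level = 0)),
               c(0.05, 0.05))
  wide <- fprWaldCI(0.5, 1e12)
  expect_equal(unname(round(wide, 4)), c(0.5, 0.5))
  expect_error(fprWaldCI(0, 100), "p0")
})

test_that("concordance, MRAE and signed bias are the stated averages", {
  expect_equal(concordanceRate(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  expect_equal(concordanceRate(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(concordanceRate(c(TRUE, TRUE, FALSE, FALSE),
                               c(TRUE, FALSE, FALSE, TRUE)), 0.5)
  expect_error(concordanceRate(TRUE, c(TRUE, FALSE)), "mismatch")

  expect_equal(mrae(c(0.1, 0.1), 0.1), 0)
  expect_equal(mrae(c(0.09, 0.11), 0.1), 0.1)
  expect_error(mrae(c(0.1), 0), "undefined")
  expect_equal(signedRelativeBias(c(0.09, 0.11), 0.1), 0)
  expect_equal(signedRelativeBias(0.05, 0.1), -0.5)
  # MRAE bounds the magnitude of the signed bias
  set.seed(51)
  est <- 0.1 + rnorm(50, sd = 0.02)
  expect_gte(mrae(est, 0.1), abs(signedRelativeBias(est, 0.1)))
})

test_that("MR inflation follows (1 + eta)^-1 exactly", {
  expect_equal(mrInflation(0), 1)
  expect_equal(mrInflation(-0.22), 1 / 0.78)
  expect_equal(round(mrInflation(-0.22), 2), 1.28)
  expect_equal(mrInflation(-0.5), 2)
  expect_error(mrInflation(-1), "eta")
  etas <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(mrInflation(etas)) < 0))  # strictly decreasing
})

test_that("Wald ratio combines associations and expected inflation", {
  est <- waldRatio(0.2, 0.1)
  expect_equal(est@waldRatio, 2)
  expect_true(is.na(est@inflationFactor))
  est2 <- waldRatio(0.2, 0.1, eta = -0.5)
  expect_equal(est2@expectedEstimate, 4)
  expect_equal(est2@inflationFactor, 2)
  est3 <- waldRatio(0.2, 0.1, eta = 0)
  expect_equal(est3@expectedEstimate, est3@waldRatio)
  expect_error(waldRatio(0.2, 0), "nonzero")
})

test_that("the scenario grid is deterministic and reports the right
           metrics per scenario type", {
  scen <- list(simulationScenario(400, 0.3, 0, 0.4, nSim = 12, seed = 52),
               simulationScenario(400, 0.3, 0.4, 0.4, nSim = 12,
                                  seed = 53))
  a <- runScenarioGrid(scen, models = c("linear", "tobit"))
  b <- runScenarioGrid(scen, models = c("linear", "tobit"))
  drop_rt <- function(x) x[setdiff(names(x), "mean_runtime_seconds")]
  expect_identical(drop_rt(a), drop_rt(b))
  null <- a[a$beta == 0, ]
  alt <- a[a$beta != 0, ]
  expect_true(all(is.na(null$sensitivity)))
  expect_true(all(!is.na(null$fpr_005)))
  expect_true(all(is.na(alt$fpr_005)))
  expect_true(all(!is.na(alt$mrae)))
  expect_true(all(alt$mrae >= 0))
  expect_true(all(a$concordance_vs_linear >= 0 &
                    a$concordance_vs_linear <= 1))
  expect_equal(a$concordance_vs_linear[a$model == "linear"], c(1, 1))
})

test_that("attenuation benchmark output is reproducible and coherent", {
  b1 <- attenuationBenchmark(nSizes = 500, betas = 0.2, mafs = 0.3,
                             censLevels = c(0.1, 0.7), nSim = 8,
                             seed = 54)
  b2 <- attenuationBenchmark(nSizes = 500, betas = 0.2, mafs = 0.3,
                             censLevels = c(0.1, 0.7), nSim = 8,
                             seed = 54)
  expect_identical(b1, b2)
  expect_equal(b1$inflation, mrInflation(b1$eta))
  lin <- b1[b1$model == "linear", ]
  expect_lt(lin$eta[lin$censored_proportion == 0.7],
            lin$eta[lin$censored_proportion == 0.1])
  expect_true(all(b1$mrae >= abs(b1$eta) - 1e-12))
})
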