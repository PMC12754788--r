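test_that("HWE genotype simulation matches binomial expectations", {
  gm <- simulateGenotypesHWE(10000, maf = 0.2, seed = 11)
  g <- drop(dosages(gm))
  counts <- tabulate(g + 1L, 3L)
  expected <- 10000 * c(0.8^2, 2 * 0.8 * 0.2, 0.2^2)  # 6400, 3200, 400
  pvals <- vapply(1:20, function(s) {
    gs <- drop(dosages(simulateGenotypesHWE(10000, 0.2, seed = 100 + s)))
    suppressWarnings(chisq.test(tabulate(gs + 1L, 3L), p = expected /
                                  10000)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.001), 19)
  expect_lt(max(abs(counts - expected)) / 10000, 0.02)
  # mean dosage symmetry at maf = 0.5
  g5 <- drop(dosages(simulateGenotypesHWE(100, 0.5, seed = 2)))
  expect_lt(abs(mean(g5) - 1), 4 * sqrt(0.5 / 100))
  expect_error(simulateGenotypesHWE(100, 0.6), "maf")
  expect_error(simulateGenotypesHWE(100, 0), "maf")
})

test_that("realized MAF has the binomial sampling distribution", {
  mafs <- vapply(1:200, function(s)
    realizedMAF(simulateGenotypesHWE(5000, 0.1, seed = 1000 + s)),
    numeric(1))
  theoSd <- sqrt(0.1 * 0.9 / (2 * 5000))
  expect_lt(abs(mean(mafs) - 0.1), 4 * theoSd / sqrt(200))
  expect_lt(abs(sd(mafs) - theoSd) / theoSd, 0.25)
})

test_that("additive phenotype recovers the simulated slope", {
  gm <- simulateGenotypesHWE(1e5, 0.2, seed = 3)
  y <- simulatePhenotype(gm, beta = 0.5, seed = 4)
  g <- drop(dosages(gm))
  fit <- lm(y ~ g)
  expect_lt(abs(coef(fit)["g"] - 0.5), 3 * summary(fit)$coef["g", 2])
  # null model: iid standard normal
  y0 <- simulatePhenotype(gm, beta = 0, seed = 5)
  expect_lt(abs(var(y0) - 1), 0.05)
  expect_lt(abs(mean(y0)), 0.02)
  expect_error(simulatePhenotype(gm, beta = c(0.1, 0.2)), "one effect")
})

test_that("percentile censoring follows the interpolation quantile rule", {
  ph0 <- applyCensoring(c(-1, 0, 2), 0)
  expect_identical(observedValues(ph0), c(-1, 0, 2))
  expect_equal(censoredProportion(ph0), 0)

  ph <- applyCensoring(as.numeric(1:10), 0.3)
  expect_equal(lodValue(ph), quantile(1:10, 0.3, names = FALSE))  # 3.7
  expect_equal(sum(isCensored(ph)), 3L)
  expect_equal(observedValues(ph)[1:3], rep(3.7, 3))
  expect_equal(observedValues(ph)[4:10], as.numeric(4:10))

  set.seed(6)
  ph9 <- applyCensoring(rnorm(10000), 0.9)
  expect_lt(abs(lodValue(ph9) - qnorm(0.9)), 0.06)
  expect_lt(abs(censoredProportion(ph9) - 0.9), 1 / 10000 + 1e-12)
  expect_true(all(observedValues(ph9) >= lodValue(ph9)))
  expect_error(applyCensoring(rnorm(10), 1), "unanalyzable")
})

test_that("fixed-threshold censoring substitutes and reports correctly", {
  ph <- applyLOD(c(-1, 0, 1), 0.5)
  expect_equal(observedValues(ph), c(0.5, 0.5, 1))
  expect_equal(censoredProportion(ph), 2 / 3)
  expect_equal(applyLOD(c(1, 2, 3), 0) |> censoredProportion(), 0)
  set.seed(7)
  expect_lt(abs(censoredProportion(applyLOD(rnorm(10000), 0)) - 0.5),
            0.02)
  expect_error(applyLOD(c(1, 2), 5), "uncensored")
})

test_that("copula LD genotypes hit target correlations and stay HWE", {
  spec <- ldBlockSpec(targetR = c(1, 0.9, 0.6, 0.3, 0, -0.5),
                      mafs = 0.3)
  gm <- simulateLDGenotypes(10000, spec, seed = 8)
  d <- dosages(gm)
  expect_true(all(d %in% c(0, 1, 2)))
  r <- drop(cor(d[, 1], d))
  expect_true(all(abs(r - spec@targetR) <= 0.05))
  expect_true(all(diff(order(r)) == diff(order(spec@targetR))))
  # marginal HWE per column
  for (j in 2:6) {
    cnt <- tabulate(d[, j] + 1L, 3L)
    expect_gt(suppressWarnings(chisq.test(
      cnt, p = c(0.49, 0.42, 0.09))$p.value), 1e-4)
  }
  # perfect LD with equal MAFs duplicates the lead column
  dup <- simulateLDGenotypes(
    500, ldBlockSpec(targetR = c(1, 1), mafs = 0.2), seed = 9)
  expect_identical(dosages(dup)[, 1], dosages(dup)[, 2])
  # infeasible correlation for discordant MAFs names the bound
  expect_error(
    simulateLDGenotypes(100, ldBlockSpec(targetR = c(1, 0.99),
                                         mafs = c(0.5, 0.05))),
    "attainable")
})

test_that("LD effect assignment follows the two strategies", {
  spec1 <- ldBlockSpec(targetR = c(0.8, 1, -0.5), mafs = 0.3,
                       leadIndex = 2L, strategy = "single_causal",
                       leadBeta = 0.1)
  expect_equal(assignLDEffects(spec1), c(0, 0.1, 0))
  spec2 <- ldBlockSpec(targetR = c(1, 0.9, -0.8, 0), mafs = 0.3,
                       strategy = "ld_proportional", leadBeta = 0.1)
  expect_equal(assignLDEffects(spec2), c(0.1, 0.09, -0.08, 0))
})

test_that("expected marginal effect matches arithmetic and OLS", {
  expect_equal(expectedMarginalEffect(0.1, 1, 0.42, 0.42), 0.1)
  expect_equal(expectedMarginalEffect(0.1, 0.9, 0.42, 0.42), 0.09)
  expect_equal(expectedMarginalEffect(0.1, 0.8, 0.42, 0.32),
               0.1 * 0.8 * sqrt(0.42 / 0.32))
  expect_error(expectedMarginalEffect(0.1, 0.8, 0.42, 0), "positive")
  # OLS cross-check: single causal lead, marginal slope at the tag SNP
  spec <- ldBlockSpec(targetR = c(1, 0.8), mafs = c(0.3, 0.25),
                      strategy = "single_causal", leadBeta = 0.1)
  gm <- simulateLDGenotypes(1e5, spec, seed = 10)
  y <- simulatePhenotype(gm, assignLDEffects(spec), seed = 11)
  tag <- dosages(gm)[, 2]
  fit <- lm(y ~ tag)
  expected <- expectedMarginalEffect(0.1, 0.8, 2 * 0.3 * 0.7,
                                     2 * 0.25 * 0.75)
  expect_lt(abs(coef(fit)["tag"] - expected),
            3 * summary(fit)$coef["tag", 2])
})

test_that("simulation is bit-reproducible given the seed", {
  a <- simulateGenotypesHWE(500, 0.2, seed = 42)
  b <- simulateGenotypesHWE(500, 0.2, seed = 42)
  expect_identical(dosages(a), dosages(b))
  spec <- ldBlockSpec(targetR = c(1, 0.7), mafs = 0.3)
  expect_identical(dosages(simulateLDGenotypes(300, spec, seed = 5)),
                   dosages(simulateLDGenotypes(300, spec, seed = 5)))
  ya <- simulatePhenotype(a, 0.1, seed = 6)
  yb <- simulatePhenotype(b, 0.1, seed = 6)
  expect_identical(ya, yb)
  expect_identical(applyCensoring(ya, 0.4), applyCensoring(yb, 0.4))
})
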