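# Model-comparison metrics, the attenuation/MR-inflation calculus, and
# the scenario-grid benchmark harness.

#' Detection rate at a significance cutoff
#'
#' Fraction of replicates with p-value below `alpha`; the sensitivity
#' (true positive rate) for non-null scenarios and the false positive
#' rate for null ones. `NA` p-values (skipped or failed fits) count as
#' non-detections.
#'
#' @param pValues numeric vector of p-values in (0, 1\].
#' @param alpha significance cutoff.
#' @return fraction in \[0, 1\].
#' @export
detectionRate <- function(pValues, alpha) {
  if (!length(pValues)) stop("empty p-value vector")
  ok <- !is.na(pValues)
  if (any(pValues[ok] <= 0 | pValues[ok] > 1))
    stop("p-values must lie in (0, 1]")
  mean(ok & pValues < alpha)
}

#' Normal (Wald) confidence interval for an empirical rate
#'
#' `p0 +/- z * sqrt(p0 (1 - p0) / n)`, truncated to \[0, 1\]. With
#' `p0 = 0.05` and `n = 1000` replicates this is the (0.0365, 0.0635)
#' band used to verify that null simulations are calibrated before
#' running non-null ones.
#'
#' @param p0 nominal rate in (0, 1).
#' @param n number of replicates.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @examples
#' round(fprWaldCI(0.05, 1000), 4)
#' @export
fprWaldCI <- function(p0, n, level = 0.95) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p0 * (1 - p0) / n)
  c(lower = max(0, p0 - half), upper = min(1, p0 + half))
}

#' Concordance rate between two significance call vectors
#'
#' Fraction of replicates in which two models agree on whether the
#' association is significant.
#'
#' @param callsA,callsB logical vectors of equal length.
#' @return fraction in \[0, 1\].
#' @export
concordanceRate <- function(callsA, callsB) {
  if (length(callsA) != length(callsB)) stop("length mismatch")
  mean(callsA == callsB)
}

#' Mean relative absolute error of effect estimates
#'
#' `mean(|(beta_i^* - beta) / beta|)` against the simulated truth.
#' Undefined for null scenarios (`trueBeta = 0`), which are evaluated by
#' false positive rate instead.
#'
#' @param estimates numeric vector of effect estimates.
#' @param trueBeta nonzero true effect.
#' @param na.rm drop failed (NA) estimates.
#' @return the mean relative absolute error.
#' @export
mrae <- function(estimates, trueBeta, na.rm = TRUE) {
  if (trueBeta == 0)
    stop("relative error undefined for trueBeta = 0; use FPR for null ",
         "scenarios")
  mean(abs((estimates - trueBeta) / trueBeta), na.rm = na.rm)
}

#' Signed mean relative bias of effect estimates
#'
#' `eta = mean((beta_i^* - beta) / beta)`; negative under attenuation
#' (systematic underestimation), as the linear model shows on censored
#' phenotypes.
#'
#' @inheritParams mrae
#' @return the signed mean relative error eta.
#' @export
signedRelativeBias <- function(estimates, trueBeta, na.rm = TRUE) {
  if (trueBeta == 0) stop("relative bias undefined for trueBeta = 0")
  mean((estimates - trueBeta) / trueBeta, na.rm = na.rm)
}

#' Mendelian randomization inflation factor implied by attenuation
#'
#' When the variant-exposure association is attenuated by a relative
#' bias `eta` (< 0 under underestimation) while the variant-outcome
#' association is unbiased, the expected Wald ratio is inflated by
#' `(1 + eta)^-1`.
#'
#' @param eta relative attenuation bias, > -1.
#' @return the multiplicative inflation factor.
#' @examples
#' mrInflation(-0.22)  # ~1.28-fold
#' @export
mrInflation <- function(eta) {
  if (any(eta <= -1)) stop("eta must be > -1")
  (1 + eta)^-1
}

#' Mendelian randomization Wald ratio
#'
#' `betaMR = betaGO / betaGE`; when an attenuation bias `eta` of the
#' exposure association is supplied, the expected (inflated) estimator
#' `betaGO / ((1 + eta) betaGE)` and the inflation factor are attached.
#'
#' @param betaGO variant-outcome association.
#' @param betaGE nonzero variant-exposure association.
#' @param eta optional relative attenuation bias of `betaGE` (> -1).
#' @return an [MrEstimate-class].
#' @export
waldRatio <- function(betaGO, betaGE, eta = NA_real_) {
  if (betaGE == 0) stop("betaGE must be nonzero")
  infl <- if (is.na(eta)) NA_real_ else mrInflation(eta)
  methods::new("MrEstimate", betaGO = betaGO, betaGE = betaGE,
               waldRatio = betaGO / betaGE, eta = as.numeric(eta),
               inflationFactor = infl,
               expectedEstimate = if (is.na(eta)) NA_real_
                                  else betaGO / ((1 + eta) * betaGE))
}

# One simulated dataset (genotype + latent phenotype) for a scenario
# replicate; sub-seed = master seed + replicate offset.
simulateReplicate <- function(n, maf, beta, seed) {
  set.seed(seed)
  g <- stats::rbinom(n, 2L, maf)
  y <- beta * g + stats::rnorm(n)
  list(g = as.numeric(g), y = y)
}

#' Attenuation benchmark of the linear and Tobit estimators
#'
#' For every combination of sample size, effect size and MAF, simulates
#' `nSim` single-SNP datasets, censors each at the requested percentile
#' levels, and fits the linear (average-tie rank-INT) and Tobit (max-tie
#' rank-INT, censored likelihood) models. Returns, per censoring level
#' and model, the signed mean relative bias eta pooled across the grid,
#' the pooled mean relative absolute error, and the implied MR Wald
#' ratio inflation factor `(1 + eta)^-1`. The same latent dataset is
#' reused across censoring levels, isolating the effect of the
#' threshold.
#'
#' @param nSizes,betas,mafs grid of sample sizes, (nonzero) effect sizes
#'   and allele frequencies.
#' @param censLevels censored proportions (default 10-90% in steps of
#'   20%).
#' @param nSim replicates per grid cell.
#' @param seed master seed; replicate r of grid cell s uses
#'   `seed + (s - 1) * nSim + r`.
#' @param models subset of `c("linear", "tobit")`.
#' @return data.frame with columns `censored_proportion`, `model`,
#'   `eta`, `mrae`, `inflation`, `n_fits`, `n_excluded` (non-converged
#'   fits, excluded from eta/MRAE).
#' @export
attenuationBenchmark <- function(nSizes = c(5000, 10000),
                                 betas = c(0.05, 0.1, 0.25),
                                 mafs = c(0.1, 0.2, 0.4),
                                 censLevels = seq(0.1, 0.9, by = 0.2),
                                 nSim = 100, seed = 1,
                                 models = c("linear", "tobit")) {
  models <- match.arg(models, several.ok = TRUE)
  grid <- expand.grid(n = nSizes, beta = betas, maf = mafs,
                      KEEP.OUT.ATTRS = FALSE)
  nl <- length(censLevels)
  rel <- array(NA_real_,
               dim = c(nrow(grid) * nSim, nl, length(models)),
               dimnames = list(NULL, NULL, models))
  row <- 0L
  for (s in seq_len(nrow(grid))) {
    for (r in seq_len(nSim)) {
      row <- row + 1L
      dat <- simulateReplicate(grid$n[s], grid$maf[s], grid$beta[s],
                               seed + (s - 1L) * nSim + r)
      for (ci in seq_len(nl)) {
        ph <- applyCensoring(dat$y, censLevels[ci])
        if ("linear" %in% models) {
          fr <- fitLinear(prepareLinearOutcome(ph), dat$g)
          if (fr@converged)
            rel[row, ci, "linear"] <- (fr@beta - grid$beta[s]) /
              grid$beta[s]
        }
        if ("tobit" %in% models) {
          fr <- fitTobit(prepareTobitOutcome(ph), dat$g)
          if (fr@converged)
            rel[row, ci, "tobit"] <- (fr@beta - grid$beta[s]) /
              grid$beta[s]
        }
      }
    }
  }
  out <- expand.grid(censored_proportion = censLevels, model = models,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$eta <- NA_real_
  out$mrae <- NA_real_
  out$n_fits <- nrow(grid) * nSim
  out$n_excluded <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- rel[, match(out$censored_proportion[i], censLevels), out$model[i]]
    out$eta[i] <- mean(v, na.rm = TRUE)
    out$mrae[i] <- mean(abs(v), na.rm = TRUE)
    out$n_excluded[i] <- sum(is.na(v))
  }
  out$inflation <- mrInflation(out$eta)
  out
}

#' Run a grid of simulation scenarios through the model suite
#'
#' For each scenario and requested model: simulate `nSim` single-SNP
#' replicates (shared across models within a replicate), preprocess with
#' the model's own transform, fit, and aggregate the comparison metrics
#' the study design calls for: sensitivity at 5e-8 for non-null
#' scenarios; FPR at 0.05 and 1e-5 for null ones; concordance of each
#' model's significance calls with the linear model's; signed relative
#' bias and MRAE (linear and Tobit only, non-null only); mean per-fit
#' process time. Non-converged fits count as non-detections and are
#' excluded from the accuracy metrics, with counts reported.
#'
#' @param scenarios list of [SimulationScenario-class] objects (or a
#'   single one).
#' @param models character subset of
#'   `c("linear", "tobit", "cox", "logistic")`.
#' @return data.frame, one row per scenario x model.
#' @export
runScenarioGrid <- function(scenarios,
                            models = c("linear", "tobit", "cox",
                                       "logistic")) {
  if (methods::is(scenarios, "SimulationScenario"))
    scenarios <- list(scenarios)
  models <- match.arg(models, several.ok = TRUE)
  res <- list()
  for (sc in scenarios) {
    nSim <- sc@nSim
    pmat <- matrix(NA_real_, nSim, length(models),
                   dimnames = list(NULL, models))
    bmat <- pmat
    cmat <- matrix(FALSE, nSim, length(models),
                   dimnames = list(NULL, models))
    tmat <- pmat
    for (r in seq_len(nSim)) {
      dat <- simulateReplicate(sc@nIndividuals, sc@maf, sc@effectSize,
                               sc@seed + r)
      ph <- applyCensoring(dat$y, sc@censoredProportion)
      for (m in models) {
        t0 <- proc.time()[["elapsed"]]
        fr <- tryCatch({
          outcome <- modelOutcome(ph, m)
          fitOne(m, outcome, dat$g, NULL)
        }, error = function(e)
          skippedFit(m, sc@nIndividuals, conditionMessage(e)))
        tmat[r, m] <- proc.time()[["elapsed"]] - t0
        pmat[r, m] <- fr@pValue
        bmat[r, m] <- fr@beta
        cmat[r, m] <- fr@converged
      }
    }
    sig <- !is.na(pmat) & pmat < 5e-8 & cmat
    for (m in models) {
      ok <- cmat[, m]
      null <- sc@effectSize == 0
      res[[length(res) + 1L]] <- data.frame(
        n = sc@nIndividuals, maf = sc@maf, beta = sc@effectSize,
        censored_proportion = sc@censoredProportion, n_sim = nSim,
        model = m,
        sensitivity = if (null) NA_real_
                      else mean(sig[, m]),
        fpr_005 = if (null) detectionRate(ifelse(ok, pmat[, m], NA),
                                          0.05) else NA_real_,
        fpr_1e5 = if (null) detectionRate(ifelse(ok, pmat[, m], NA),
                                          1e-5) else NA_real_,
        concordance_vs_linear = if ("linear" %in% models)
          concordanceRate(sig[, m], sig[, "linear"]) else NA_real_,
        eta = if (!null && m %in% c("linear", "tobit"))
          signedRelativeBias(bmat[ok, m], sc@effectSize) else NA_real_,
        mrae = if (!null && m %in% c("linear", "tobit"))
          mrae(bmat[ok, m], sc@effectSize) else NA_real_,
        mean_runtime_seconds = mean(tmat[, m]),
        n_excluded = sum(!ok),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
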