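# Seeded simulation engine: HWE genotypes, additive phenotypes,
# percentile/fixed-threshold censoring, and Gaussian-copula LD blocks.

#' Simulate a single SNP under Hardy-Weinberg equilibrium
#'
#' Draws each individual's dosage as Binomial(2, maf), so genotype counts
#' fluctuate around the HWE expectations N p^2, 2 N p q, N q^2.
#'
#' @param n sample size (>= 2).
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed.
#' @param variantId variant label.
#' @param position 1-based base-pair position.
#' @return a single-column [GenotypeMatrix-class]; `realizedMAF()` reports
#'   the sample allele frequency (2 n2 + n1) / (2 N).
#' @examples
#' gm <- simulateGenotypesHWE(1000, maf = 0.2, seed = 1)
#' realizedMAF(gm)
#' @export
simulateGenotypesHWE <- function(n, maf, seed = NULL, variantId = "snp1",
                                 position = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rbinom(n, 2L, maf)
  GenotypeMatrix(matrix(as.numeric(g), ncol = 1),
                 variantIds = variantId, positions = position)
}

#' Simulate an additive phenotype
#'
#' `y = g %*% beta + epsilon` with standard normal noise; the additive
#' single-SNP case is `y = beta * g + N(0, 1)`.
#'
#' @param genotypes a [GenotypeMatrix-class], dosage matrix (samples x
#'   variants) or dosage vector.
#' @param beta effect size(s); recycled to a scalar for a single variant,
#'   otherwise one per variant.
#' @param seed optional integer seed.
#' @return numeric vector of latent (pre-censoring) phenotype values.
#' @export
simulatePhenotype <- function(genotypes, beta, seed = NULL) {
  g <- if (methods::is(genotypes, "GenotypeMatrix")) dosages(genotypes)
       else as.matrix(genotypes)
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (length(beta) != ncol(g))
    stop("need one effect size per variant")
  if (!is.null(seed)) set.seed(seed)
  drop(g %*% beta) + stats::rnorm(nrow(g))
}

#' Censor a phenotype at an empirical percentile
#'
#' The limit of detection is set to the requested empirical quantile of
#' the latent values (linear-interpolation quantile, type 7), and values
#' below it are substituted with the threshold: `observed = max(y, LOD)`.
#'
#' @param latent numeric vector of latent phenotype values.
#' @param censoredProportion target fraction below the LOD, in \[0, 1).
#' @return a [CensoredPhenotype-class] retaining the latent values.
#' @examples
#' ph <- applyCensoring(rnorm(100), 0.3)
#' censoredProportion(ph)
#' @export
applyCensoring <- function(latent, censoredProportion) {
  if (censoredProportion < 0 || censoredProportion >= 1)
    stop("censoredProportion must lie in [0, 1); an all-censored ",
         "phenotype is unanalyzable")
  if (censoredProportion == 0)
    return(CensoredPhenotype(latent, lod = -Inf,
                             isCensored = rep(FALSE, length(latent)),
                             latent = latent))
  lod <- stats::quantile(latent, censoredProportion, type = 7,
                         names = FALSE)
  CensoredPhenotype(pmax(latent, lod), lod = lod,
                    isCensored = latent < lod, latent = latent)
}

#' Censor a phenotype at a fixed threshold
#'
#' Same substitution rule as [applyCensoring()] but with a user-supplied
#' LOD, for exploring a gradient of censoring on one dataset.
#'
#' @param latent numeric vector of latent phenotype values.
#' @param lodValue finite limit of detection; must leave at least one
#'   observation uncensored.
#' @return a [CensoredPhenotype-class]; `censoredProportion()` reports the
#'   realized fraction.
#' @export
applyLOD <- function(latent, lodValue) {
  if (!is.finite(lodValue)) stop("lodValue must be finite")
  if (lodValue >= max(latent))
    stop("lodValue >= max(latent): no uncensored observations remain")
  CensoredPhenotype(pmax(latent, lodValue), lod = lodValue,
                    isCensored = latent < lodValue, latent = latent)
}

# --- Gaussian copula machinery for LD blocks ------------------------------

# Latent-normal cutpoints putting HWE mass p^2, 2pq, q^2 on dosages 0/1/2.
genotypeCutpoints <- function(maf) {
  p <- 1 - maf
  stats::qnorm(c(p^2, p^2 + 2 * p * maf))
}

# Bivariate standard normal CDF P(Z1 <= h, Z2 <= k; rho) by reducing to a
# one-dimensional integral over the conditional distribution.
bvnCdf <- function(h, k, rho) {
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    if (k == Inf) return(stats::pnorm(h))
  }
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho > 1 - 1e-10) return(stats::pnorm(min(h, k)))
  if (rho < -1 + 1e-10) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((k - rho * z) / s),
    lower = -Inf, upper = h, rel.tol = 1e-10)$value
}

# Genotype-scale Pearson correlation implied by latent correlation rho for
# two copula-thresholded HWE dosages. Uses D = I(z > t1) + I(z > t2), so
# E[D1 D2] is a sum of four upper-orthant probabilities.
genotypeCorrFromLatent <- function(rho, maf1, maf2) {
  t1 <- genotypeCutpoints(maf1)
  t2 <- genotypeCutpoints(maf2)
  upper <- function(a, b)
    1 - stats::pnorm(a) - stats::pnorm(b) + bvnCdf(a, b, rho)
  e12 <- upper(t1[1], t2[1]) + upper(t1[1], t2[2]) +
         upper(t1[2], t2[1]) + upper(t1[2], t2[2])
  mu1 <- 2 * maf1; mu2 <- 2 * maf2
  s1 <- sqrt(2 * maf1 * (1 - maf1)); s2 <- sqrt(2 * maf2 * (1 - maf2))
  (e12 - mu1 * mu2) / (s1 * s2)
}

# Invert target genotype-scale correlation to the latent scale via a
# tabulated curve with a monotone (Hyman) spline. Cached per MAF pair.
latentRhoForTarget <- local({
  cache <- new.env(parent = emptyenv())
  function(targetR, maf1, maf2) {
    if (abs(targetR) < 1e-12) return(0)
    key <- paste(signif(maf1, 10), signif(maf2, 10), sep = "|")
    fun <- cache[[key]]
    if (is.null(fun)) {
      # Dense core plus near-boundary points; the endpoints +/-1 are the
      # exact co-/antimonotone limits, so the attainable range is exact.
      grid <- c(-1, -0.9999, -0.999, -0.99,
                seq(-0.98, 0.98, length.out = 57),
                0.99, 0.999, 0.9999, 1)
      gr <- vapply(grid, genotypeCorrFromLatent, numeric(1),
                   maf1 = maf1, maf2 = maf2)
      keep <- c(TRUE, diff(gr) > 1e-12)  # strict monotonicity for spline
      fun <- stats::splinefun(gr[keep], grid[keep], method = "hyman")
      attr(fun, "range") <- range(gr)
      cache[[key]] <- fun
    }
    bounds <- attr(fun, "range")
    if (targetR < bounds[1] - 1e-8 || targetR > bounds[2] + 1e-8)
      stop(sprintf(
        "target genotype correlation %.4g is infeasible for MAFs %.3g/%.3g; attainable range is [%.4g, %.4g]",
        targetR, maf1, maf2, bounds[1], bounds[2]))
    targetR <- min(bounds[2], max(bounds[1], targetR))
    min(1, max(-1, fun(targetR)))
  }
})

#' Simulate an LD-correlated genotype block by a Gaussian copula
#'
#' Latent multivariate normal variables with a one-factor correlation
#' structure around the lead SNP are thresholded at the HWE cumulative
#' genotype frequencies of each variant, so marginals obey HWE while the
#' genotype-scale Pearson correlation with the lead matches
#' `targetR` (the latent correlation is obtained by numerically inverting
#' the genotype-scale correlation curve). A variant with `targetR = 1`
#' and the lead's MAF reproduces the lead column exactly.
#'
#' @param n sample size.
#' @param spec an [LdBlockSpec-class].
#' @param seed optional integer seed.
#' @return a [GenotypeMatrix-class] with one column per variant in the
#'   block.
#' @export
simulateLDGenotypes <- function(n, spec, seed = NULL) {
  stopifnot(methods::is(spec, "LdBlockSpec"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(spec@targetR)
  lead <- spec@leadIndex
  loadings <- vapply(seq_len(m), function(j) {
    if (j == lead) return(1)
    latentRhoForTarget(spec@targetR[j], spec@mafs[lead], spec@mafs[j])
  }, numeric(1))
  w <- stats::rnorm(n)
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    lam <- loadings[j]
    z <- if (abs(lam) >= 1) sign(lam) * w
         else lam * w + sqrt(1 - lam^2) * stats::rnorm(n)
    ct <- genotypeCutpoints(spec@mafs[j])
    d[, j] <- (z > ct[1]) + (z > ct[2])
  }
  GenotypeMatrix(d, variantIds = paste0("snp", seq_len(m)),
                 positions = spec@positions)
}

#' Per-variant effect sizes implied by an LD-block strategy
#'
#' `single_causal` places `leadBeta` on the lead SNP and 0 elsewhere;
#' `ld_proportional` scales effects by the signed correlation with the
#' lead: `beta_j = leadBeta * targetR[j]`.
#'
#' @param spec an [LdBlockSpec-class].
#' @return numeric vector of effect sizes, one per variant.
#' @export
assignLDEffects <- function(spec) {
  stopifnot(methods::is(spec, "LdBlockSpec"))
  if (spec@strategy == "single_causal") {
    b <- rep(0, length(spec@targetR))
    b[spec@leadIndex] <- spec@leadBeta
    b
  } else {
    spec@leadBeta * spec@targetR
  }
}

#' Expected marginal effect of a tag SNP under a single causal variant
#'
#' When only the lead SNP is causal with effect `betaLead`, the marginal
#' (single-SNP) regression slope at a tag SNP j in LD with the lead is
#' `betaLead * r * sqrt(Var(G_lead) / Var(G_j))`, with `r` the signed
#' dosage correlation.
#'
#' @param betaLead causal effect at the lead SNP.
#' @param r signed dosage correlation between tag and lead.
#' @param varLead,varJ dosage variances of the lead and tag SNPs
#'   (`varJ > 0`).
#' @return the expected marginal slope at the tag SNP.
#' @export
expectedMarginalEffect <- function(betaLead, r, varLead, varJ) {
  if (varJ <= 0) stop("varJ must be positive")
  betaLead * r * sqrt(varLead / varJ)
}
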