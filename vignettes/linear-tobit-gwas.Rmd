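---
title: "Association testing for biomarkers with below-detection-limit measurements"
author: "tobitGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association testing for biomarkers with below-detection-limit measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobitGWAS)
```

## The problem

High-throughput proteomics and metabolomics assays report a limit of
detection (LOD) per analyte; samples whose true level falls below it are
*left-censored* — we only know they are somewhere below the threshold.
When such a trait is the outcome of a genome-wide association study
(GWAS), the standard pipeline (substitute censored values at the LOD,
rank-based inverse normal transform, linear regression) keeps its type-I
error control and most of its detection power, but the genotype effect
estimates are systematically attenuated, increasingly so as the censored
fraction grows. Downstream uses that consume effect sizes rather than
p-values — Mendelian randomization (MR) Wald ratios, polygenic scores,
meta-analysis — inherit that bias: if the variant–exposure association
is underestimated by a relative factor $\eta < 0$, the expected MR ratio
is inflated by $(1+\eta)^{-1}$.

This package implements the four estimators usually considered for such
traits, a seeded simulation engine that reproduces the study design used
to compare them, the evaluation metrics, and the practical answer: a
**two-step Linear–Tobit scheme** — screen every variant with fast linear
regression, clump the hits into independent loci, and refit only the
lead variants with the Tobit (censored Gaussian) likelihood to recover
unbiased effect estimates.

## Data model

Phenotypes follow the additive single-SNP model
$y = \beta g + \varepsilon,\ \varepsilon \sim N(0,1)$, with dosage
$g \in \{0,1,2\}$ drawn as $\mathrm{Binomial}(2, q)$ so genotype counts
fluctuate around the Hardy–Weinberg expectations $(Np^2, 2Npq, Nq^2)$.
Censoring substitutes values below the LOD with the LOD itself,
$y_{obs} = \max(y, \mathrm{LOD})$; the simulator sets the LOD at an
empirical percentile of each replicate's latent values (the
linear-interpolation quantile, R's type 7 — the exact rule only matters
for toy-sized vectors, but it is fixed and documented so the
enumeration tests are exact). The percentile is recomputed per
replicate, i.e. each simulated dataset is censored at its own empirical
quantile; a fixed-threshold variant (`applyLOD()`) covers designs that
sweep a gradient of LODs over one dataset.

## The four estimators

**Linear.** Rank-based inverse normal transformation (INT),
$y^* = \Phi^{-1}\!\big((r - k)/(n - 2k + 1)\big)$ with Blom's offset
$k = 3/8$, applied to the full substituted vector. The censored block is
one large tied group; with the `average` tie policy every censored
sample is imputed at the central rank of that block. Ordinary least
squares follows. The offset is exposed as a parameter because published
conventions vary; $3/8$ is the default of the transform tooling this
field uses.

**Tobit.** The same INT but with the `max` tie policy, which parks the
whole censored block at the largest rank of its tied group — the
transformed-scale detection limit $c$. The censored Gaussian likelihood
$$\ell(\beta,\sigma) = \sum_{uncens}\left[\log\phi\!\left(\tfrac{y_i - x_i^\top\beta}{\sigma}\right) - \log\sigma\right] + \sum_{cens}\log\Phi\!\left(\tfrac{c - x_i^\top\beta}{\sigma}\right)$$
is maximized in Olsen's reparameterization
$(\gamma, h) = (\beta/\sigma,\ 1/\sigma)$, in which it is globally
concave, by damped Newton steps with analytic gradient and Hessian from
an OLS warm start. This typically converges in 5–8 iterations at
biobank-scale $n$; convergence is declared when the per-observation
gradient norm falls below $10^{-6}$, with a BFGS restart on the same
surface before flagging failure. Standard errors come from the observed
information with a delta-method map back to $\beta$. With nothing
censored the threshold is placed below all values and the closed-form
OLS solution (the uncensored MLE) is returned, so the Tobit fit
coincides with the linear one exactly — a limit the tests pin at
$10^{-6}$. We use ties among *uncensored* values (possible in real
data) under the same declared policy; only censored ties arise in
simulation.

**Cox.** The left-censored scale is flipped to a right-censored
pseudo-time, $y_{cox} = \max(y_{obs}) - y_{obs}$, with detections
($y_{obs} > \mathrm{LOD}$) as events, and an Efron-corrected partial
likelihood is fitted. Efron is the standard default and is benign here:
with continuous phenotypes the only tie is the censored block, which
consists entirely of non-events. The proportional hazards (PH)
assumption is exactly what a genotype *association* violates — a
genotype that shifts the biomarker shifts the hazard differentially
along the flipped scale — so the Grambsch–Therneau Schoenfeld residual
test (Kaplan–Meier time transform by default, identity available) is
wired in and is expected to reject under a true effect. The acceptance
suite reproduces this: with a non-null genotype the PH test rejects at
0.05 in the majority of replicates, which is the substantive argument
against the Cox route for censored biomarkers.

**Logistic.** The trait is collapsed to the detection indicator
$\delta = I(y_{obs} > \mathrm{LOD})$ and fitted by IRLS. The resolution
loss costs sensitivity everywhere except near 50% censoring, where the
classes are balanced. Fits with a minority class under 10 observations
are refused with a diagnostic instead of returning unstable estimates,
and separation is flagged as non-convergence.

All four engines accept covariates identically, skip near-monomorphic
variants (minor allele count < 3) with an `NA` row rather than an
exception, and report two-sided Wald p-values — the GWAS convention.

## The two-step scheme

`linearTobitScheme()` composes `gwasScreen()` (linear),
`clumpVariants()` and `refineTobit()`. Clumping is the greedy standard:
take the smallest-p unassigned variant with $p < p_1$ as index (ties on
p broken by smaller base-pair position, a rule we fix explicitly because
external tools leave it to their internal sort), assign every unassigned
variant with $p < p_2$, $r^2 \ge$ threshold and distance within the
window, repeat. Defaults $p_1 = 5\times 10^{-8}$, $p_2 = 10^{-4}$,
$r^2 = 0.1$, 1000 kb. LD is computed from the analysis sample's own
dosages — all in-scope data are simulated, so there is no external
reference panel to defer to. By default only clump index variants are
refit with Tobit; `refineAll = TRUE` refines every genome-wide
significant variant instead, since either reading of "refine the
detected variants" is defensible. The set of leads is decided entirely
by the screening pass, so it is invariant to whether refinement runs,
and the number of censored-likelihood fits equals the number of leads —
that is the efficiency contract that makes the scheme scale.

## LD-block simulation

`simulateLDGenotypes()` draws correlated dosages through a Gaussian
copula: a latent standard normal per variant, cut at
$\Phi^{-1}(p^2)$ and $\Phi^{-1}(p^2 + 2pq)$ so the marginal obeys HWE.
Thresholding shrinks correlation, so the latent correlation is found by
numerically inverting the genotype-scale correlation curve (computed by
one-dimensional quadrature of the bivariate normal orthant
probabilities, tabulated over a latent-$\rho$ grid and inverted with a
monotone Hyman spline; infeasible targets are refused with the
attainable bound named). Correlations are specified against a lead SNP
and realized through a one-factor structure
$z_j = \rho_j W + \sqrt{1-\rho_j^2}\,e_j$, which is positive
semi-definite by construction. Effects are assigned either to the lead
only (`single_causal`, where tag SNPs acquire the marginal effect
$\beta_{lead}\, R\, \sqrt{\mathrm{Var}(G_{lead})/\mathrm{Var}(G_j)}$)
or proportionally to the signed correlation (`ld_proportional`).

What this emulates: a locus with a realistic LD gradient around a lead
variant and exact HWE marginals. What it does not: haplotype structure
beyond pairwise one-factor correlation, allele-frequency-dependent LD
decay, genotyping error, relatedness, or non-additive genetic effects —
passing tests therefore validate the estimators under the stated
generating model, not robustness to those realities. Interaction terms
are deliberately absent. Where the original locus design drew real
participants, the synthetic analogue draws fresh copula genotypes per
replicate.

## Metrics and the MR calculus

Sensitivity is the fraction of replicates with $p < 5\times10^{-8}$;
false positive rates are reported at 0.05 and $10^{-5}$ (the genome-wide
cutoff would give identically zero). Calibration of the simulation setup
itself is checked against the $\mathrm{Binomial}(1000, 0.05)$ Wald
interval $(0.0365, 0.0635)$ before any non-null run. Accuracy is
reported two ways: the mean relative absolute error
$\mathrm{MRAE} = \frac{1}{n}\sum_i |(\beta_i^* - \beta)/\beta|$ and the
signed mean relative bias
$\eta = \frac{1}{n}\sum_i (\beta_i^* - \beta)/\beta$. These answer
different questions: MRAE includes per-replicate sampling noise and is
bounded away from zero at moderate sample sizes even for an unbiased
estimator, while $\eta$ isolates the systematic component; headline
"relative error" figures for estimator accuracy are magnitudes of
$\eta$, and both statistics are emitted so neither needs to stand in
for the other. The MR consequence is closed-form:
`mrInflation(eta)` $= (1+\eta)^{-1}$ and
`waldRatio(betaGO, betaGE, eta)` give the expected inflated causal
estimate.

## Problem sizes and reproducibility

The benchmark grid we run by default is
$N \in \{5000, 10000\}$, $\beta \in \{0.05, 0.1, 0.25\}$,
$\mathrm{MAF} \in \{0.1, 0.2, 0.4\}$, censoring 10–90% in steps of 20%,
100 replicates per cell — 9000 fits per model — which puts the Monte
Carlo standard error of each pooled $\eta$ under one percentage point
while keeping a desk-scale runtime. Sensitivity-ranking runs use
$N = 10^4$, $\beta = 0.1$, MAF 0.4 with 200 replicates. Every stochastic
path takes a master seed; scenario replicate $r$ of grid cell $s$ uses
`seed + (s-1)*nSim + r`, so any single replicate can be regenerated in
isolation and identical (scenario, seed) pairs are bit-identical.

```{r example, eval = FALSE}
bench <- attenuationBenchmark(nSim = 100, seed = 1)
subset(bench, model == "linear",
       select = c(censored_proportion, eta, inflation))
```

## Known limitations

* No genetic relatedness adjustment: the Tobit engine is a fixed-effects
  model; mixed-model or GRM-aware extensions are out of scope.
* One LOD per trait. Batch-varying detection limits are rejected at
  read time rather than silently averaged; per-batch analysis plus
  meta-analysis is the supported route.
* The additive dosage coding is assumed throughout; dominance or other
  genetic models will be mis-specified by all four engines.
* The Cox engine is the plain partial-likelihood fit; frailty or
  saddlepoint-accelerated variants used by genome-scale survival tools
  are not reproduced, so cross-tool numeric parity is not asserted.
* p-values are Wald-based everywhere; at tiny samples or extreme
  censored fractions likelihood-ratio intervals would behave better.
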