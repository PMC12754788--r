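# tobitGWAS

Genome-wide association testing for quantitative biomarkers in which a
fraction of measurements falls below the assay limit of detection (LOD).
Large-scale proteomics and metabolomics panels routinely report such
left-censored values; substituting them at the LOD and running the
standard rank-INT + linear regression pipeline keeps detection power and
type-I error, but systematically **attenuates effect estimates** — and
any downstream consumer of effect sizes (Mendelian randomization,
polygenic scores, meta-analysis) inherits the bias. This package is for
statistical geneticists and biostatisticians who need to quantify that
bias, compare the candidate models, and run the practical fix.

## What it implements

* **Four estimators** for a left-censored outcome regressed on genotype
  dosage (+ covariates):
  * *linear*: rank-based inverse normal transform (INT),
    `y* = Φ⁻¹((r − 3/8)/(n + 1/4))`, censored block imputed at its
    **average** tied rank, then OLS;
  * *Tobit*: INT with the **max** tie policy so the censored block sits
    at the transformed-scale LOD `c`, then the censored Gaussian
    likelihood
    `ℓ(β,σ) = Σ_uncens[log φ((yᵢ−xᵢᵀβ)/σ) − log σ] + Σ_cens log Φ((c−xᵢᵀβ)/σ)`,
    maximized by damped Newton in the concave reparameterization
    (β/σ, 1/σ);
  * *Cox*: flip to right-censored pseudo-time
    `y_cox = max(y_obs) − y_obs` with detections as events, Efron
    partial likelihood, plus the Schoenfeld-residual test that exposes
    the proportional-hazards violation a real genotype effect causes;
  * *logistic*: detection indicator `I(y_obs > LOD)` by IRLS.
* **The two-step Linear–Tobit scheme**: linear screen of all variants →
  greedy LD clumping (`p1 = 5e−8`, `p2 = 1e−4`, `r² = 0.1`, 1000 kb) →
  Tobit refit of the clump leads only, so the expensive censored
  likelihood runs once per locus instead of once per variant.
* **A seeded simulation engine**: Hardy–Weinberg genotypes
  (`Binomial(2, q)`), additive phenotypes `y = βg + N(0,1)`, percentile
  or fixed-threshold censoring, and Gaussian-copula LD blocks with
  target correlations against a lead SNP (single-causal or
  LD-proportional effect assignment).
* **Evaluation metrics and the MR calculus**: sensitivity at 5e−8, FPR
  at 0.05 and 1e−5 with the Binomial Wald calibration band, concordance
  between models, MRAE and the signed relative bias η, and the implied
  Wald-ratio inflation `(1 + η)⁻¹`.

## Worked example

A five-variant locus around a causal lead SNP (β = 0.25), 10 000
samples, 50% of phenotype values censored at the LOD:

```r
library(tobitGWAS)
spec <- ldBlockSpec(targetR = c(1, 0.9, 0.8, 0.5, 0.2),
                    mafs = c(0.3, 0.3, 0.25, 0.3, 0.35),
                    strategy = "single_causal", leadBeta = 0.25)
gm <- simulateLDGenotypes(10000, spec, seed = 1)
ph <- applyCensoring(simulatePhenotype(gm, assignLDEffects(spec), seed = 2), 0.5)
res <- linearTobitScheme(gm, ph)
res
#> GwasTable: 5 variants, model = linear
#>   1 clumps (1 index variants)
#>   1 variants Tobit-refined
#>   variant_id position     maf     n  model       beta         se      p_value
#> 1       snp1  1000000 0.29915 10000 linear 0.22303056 0.01282247 8.807327e-67
#> 2       snp2  1010000 0.30045 10000 linear 0.20488931 0.01286689 2.133519e-56
#> 3       snp3  1020000 0.25010 10000 linear 0.18908293 0.01367948 4.644319e-43
#> 4       snp4  1030000 0.29940 10000 linear 0.10496958 0.01306685 1.056093e-15
#> 5       snp5  1040000 0.34835 10000 linear 0.03006661 0.01252825 1.641748e-02
#>   converged reason clump_id is_index refined_beta refined_se    refined_p
#> 1      TRUE   <NA>        1     TRUE    0.2803295 0.01648432 7.434415e-65
#> ...
```

The linear screen finds the locus (all four correlated variants join the
lead's clump) but underestimates the lead effect (0.223 vs the simulated
0.25, a ~11% attenuation at 50% censoring); the Tobit refit of the
single lead returns an estimate consistent with the truth
(0.280 ± 0.016). Had the attenuated screening estimate been used as an
MR exposure association, the Wald ratio would have been inflated by
`mrInflation(-0.108)` ≈ 1.12-fold — and the package's benchmark shows
this factor grows hyperbolically with the censored fraction.

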