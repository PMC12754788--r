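Package: tobitGWAS
Title: Two-Step Linear-Tobit Association Testing for Phenotypes with
    Below-Detection-Limit Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, transformation, and regression machinery for
    genome-wide association studies (GWAS) of quantitative biomarkers in
    which a fraction of measurements falls below the assay limit of
    detection (LOD) and is left-censored at that limit. Implements the
    four modelling strategies commonly considered for such traits --
    linear regression on rank-based inverse normal transformed values,
    Tobit (censored Gaussian) maximum likelihood, a Cox proportional
    hazards flip of the censored scale, and logistic regression on the
    detection indicator -- together with a two-step Linear-Tobit scheme
    (fast linear screening, greedy LD clumping, Tobit refinement of lead
    variants), a seeded simulation engine (Hardy-Weinberg genotypes,
    additive effects, percentile censoring, Gaussian-copula LD blocks),
    model-comparison metrics, and the attenuation-driven inflation
    calculus for Mendelian randomization Wald ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
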