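#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm rbinom quantile qnorm pnorm dnorm pt cor var sd
#'   optim optimHess integrate splinefun complete.cases glm.fit binomial
#'   setNames runif
#' @importFrom utils read.delim write.table head
NULL

#' Genotype dosage matrix with variant metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding an
#' additive dosage assay (variants as rows, samples as columns; each entry
#' counts copies of the coded allele, 0/1/2, possibly fractional after
#' mean-imputation of missing calls) together with per-variant metadata:
#' identifier, base-pair position (1-based) and realized allele frequency
#' of the coded allele, computed as (2 n2 + n1) / (2 N).
#'
#' @slot .
#' Use [GenotypeMatrix()] to construct and the accessors [dosages()],
#' [variantIds()], [variantPositions()], [realizedMAF()] to inspect.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!is.numeric(d))
    return("dosages must be numeric")
  if (any(!is.finite(d)))
    return("dosages must be finite (impute missing calls before construction)")
  if (any(d < 0 | d > 2))
    return("dosages must lie in [0, 2]")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("variant_id", "position", "maf")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  TRUE
})

#' Left-censored phenotype
#'
#' Observed biomarker values after substitution at the limit of detection
#' (LOD): `observed = max(latent, lod)`, with the censoring indicator
#' recording which latent values fell below the LOD. The latent vector is
#' retained when the object comes from the simulator (length zero
#' otherwise).
#'
#' @slot observed numeric, substituted measurements (never below `lod`).
#' @slot lod numeric(1), the limit of detection (`-Inf` when no censoring
#'   was applied).
#' @slot isCensored logical, `TRUE` where the latent value was below LOD.
#' @slot latent numeric, pre-censoring values (simulation only; may be
#'   empty).
#'
#' @exportClass CensoredPhenotype
setClass("CensoredPhenotype",
  representation(observed = "numeric", lod = "numeric",
                 isCensored = "logical", latent = "numeric"))

setValidity("CensoredPhenotype", function(object) {
  n <- length(object@observed)
  if (length(object@isCensored) != n)
    return("observed and isCensored must have equal length")
  if (length(object@lod) != 1L)
    return("lod must be a single value")
  if (is.na(object@lod)) return("lod must not be NA")
  if (any(is.na(object@observed))) return("observed values must not be NA")
  if (any(object@observed < object@lod))
    return("observed values must not lie below the LOD")
  if (length(object@latent) && length(object@latent) != n)
    return("latent, when present, must match observed in length")
  if (all(object@isCensored))
    return("all-censored phenotype is unanalyzable")
  TRUE
})

#' Rank-based inverse normal transformed outcome
#'
#' Values on the normal-quantile scale, `qnorm((r - k) / (n - 2k + 1))`
#' with ranks `r` assigned under the stated tie policy and offset `k`
#' (Blom's 3/8 by default). For the Tobit preparation (`max` ties) the
#' common transformed value of the censored block is recorded as the
#' transformed-scale censoring threshold; it is set below `min(values)`
#' when nothing is censored, so the censored-likelihood fit degenerates to
#' the uncensored MLE.
#'
#' @slot values numeric, transformed outcome.
#' @slot tiesPolicy character(1), `"average"` or `"max"`.
#' @slot offset numeric(1), the rank offset k.
#' @slot censorThreshold numeric(1), transformed-scale LOD (may be `-Inf`
#'   conceptually; stored as a value below all `values` when uncensored),
#'   or length zero for the linear preparation.
#'
#' @exportClass TransformedOutcome
setClass("TransformedOutcome",
  representation(values = "numeric", tiesPolicy = "character",
                 offset = "numeric", censorThreshold = "numeric"))

setValidity("TransformedOutcome", function(object) {
  if (!object@tiesPolicy %in% c("average", "max"))
    return("tiesPolicy must be 'average' or 'max'")
  if (length(object@censorThreshold) > 1L)
    return("censorThreshold must have length 0 or 1")
  TRUE
})

#' Flipped outcome for the Cox proportional hazards approach
#'
#' Left-censored measurements recast as right-censored pseudo-times:
#' `pseudoTime = max(observed) - observed`, with `event = (observed > LOD)`
#' so that above-LOD measurements are "events" and the censored block sits
#' at the largest pseudo-time as non-events.
#'
#' @slot pseudoTime numeric, non-negative flipped scale.
#' @slot event logical, detection indicator.
#'
#' @exportClass CoxOutcome
setClass("CoxOutcome",
  representation(pseudoTime = "numeric", event = "logical"))

setValidity("CoxOutcome", function(object) {
  if (length(object@pseudoTime) != length(object@event))
    return("pseudoTime and event must have equal length")
  if (any(object@pseudoTime < 0)) return("pseudoTime must be non-negative")
  TRUE
})

#' Result of a single-variant regression fit
#'
#' @slot model character(1): `"linear"`, `"tobit"`, `"cox"` or
#'   `"logistic"`.
#' @slot beta numeric(1), genotype coefficient (slope on the transformed
#'   scale, log hazard, or log odds; `NA` for skipped fits).
#' @slot se numeric(1), standard error.
#' @slot pValue numeric(1), two-sided Wald p-value.
#' @slot sigma numeric(1), residual scale (linear/Tobit; `NA` otherwise).
#' @slot converged logical(1).
#' @slot nUsed integer(1), observations used.
#' @slot diagnostics list, model-specific extras (e.g. the underlying
#'   `coxph` fit, skip reasons, optimizer details).
#'
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "character", beta = "numeric", se = "numeric",
                 pValue = "numeric", sigma = "numeric",
                 converged = "logical", nUsed = "integer",
                 diagnostics = "list"),
  prototype(sigma = NA_real_, converged = FALSE, diagnostics = list()))

setValidity("FitResult", function(object) {
  if (!object@model %in% c("linear", "tobit", "cox", "logistic"))
    return("unknown model tag")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    return("pValue must lie in (0, 1]")
  TRUE
})

#' Per-variant GWAS results
#'
#' One row per variant with screening estimates, optional clump
#' assignments and optional Tobit refinement columns, plus provenance
#' metadata (model, tie policy, INT offset, clump parameters, seed).
#'
#' @slot table data.frame with columns `variant_id`, `position`, `maf`,
#'   `n`, `model`, `beta`, `se`, `p_value`, `converged`, `reason` and,
#'   after clumping/refinement, `clump_id`, `is_index`, `refined_beta`,
#'   `refined_se`, `refined_p`, `refined_converged`.
#' @slot metadata list of provenance fields.
#'
#' @exportClass GwasTable
setClass("GwasTable",
  representation(table = "data.frame", metadata = "list"),
  prototype(metadata = list()))

#' Simulation scenario for the single-SNP engine
#'
#' @slot nIndividuals integer(1), sample size N.
#' @slot maf numeric(1), minor allele frequency in (0, 0.5].
#' @slot effectSize numeric(1), additive effect beta (0 under the null).
#' @slot censoredProportion numeric(1) in [0, 1).
#' @slot nSim integer(1), number of replicates.
#' @slot seed integer(1), master seed for the scenario.
#'
#' @exportClass SimulationScenario
setClass("SimulationScenario",
  representation(nIndividuals = "integer", maf = "numeric",
                 effectSize = "numeric", censoredProportion = "numeric",
                 nSim = "integer", seed = "integer"))

setValidity("SimulationScenario", function(object) {
  if (object@nIndividuals < 2L) return("nIndividuals must be >= 2")
  if (object@maf <= 0 || object@maf > 0.5)
    return("maf must lie in (0, 0.5]")
  if (object@censoredProportion < 0 || object@censoredProportion >= 1)
    return("censoredProportion must lie in [0, 1)")
  if (object@nSim < 1L) return("nSim must be >= 1")
  TRUE
})

#' Specification of an LD-correlated genotype block
#'
#' Describes a locus around a lead SNP: target genotype-scale signed
#' correlations of each variant with the lead (the lead itself carries
#' 1), per-variant allele frequencies and positions, and how effects are
#' assigned (`single_causal`: only the lead has effect `leadBeta`;
#' `ld_proportional`: variant j gets `leadBeta * targetR[j]`).
#'
#' @slot leadIndex integer(1).
#' @slot targetR numeric, signed correlations with the lead, |r| <= 1.
#' @slot mafs numeric, allele frequencies in (0, 0.5].
#' @slot strategy character(1), `"single_causal"` or `"ld_proportional"`.
#' @slot leadBeta numeric(1).
#' @slot positions integer, 1-based base-pair positions.
#'
#' @exportClass LdBlockSpec
setClass("LdBlockSpec",
  representation(leadIndex = "integer", targetR = "numeric",
                 mafs = "numeric", strategy = "character",
                 leadBeta = "numeric", positions = "integer"))

setValidity("LdBlockSpec", function(object) {
  m <- length(object@targetR)
  if (length(object@mafs) != m || length(object@positions) != m)
    return("targetR, mafs and positions must have equal length")
  if (object@leadIndex < 1L || object@leadIndex > m)
    return("leadIndex out of range")
  if (any(abs(object@targetR) > 1)) return("|targetR| must be <= 1")
  if (abs(object@targetR[object@leadIndex] - 1) > 1e-12)
    return("the lead variant must have targetR = 1")
  if (any(object@mafs <= 0 | object@mafs > 0.5))
    return("mafs must lie in (0, 0.5]")
  if (!object@strategy %in% c("single_causal", "ld_proportional"))
    return("strategy must be 'single_causal' or 'ld_proportional'")
  TRUE
})

#' Mendelian randomization Wald ratio with attenuation-implied inflation
#'
#' @slot betaGO numeric(1), variant-outcome association.
#' @slot betaGE numeric(1), variant-exposure association (nonzero).
#' @slot waldRatio numeric(1), betaGO / betaGE.
#' @slot eta numeric(1), relative attenuation bias of the exposure
#'   association (NA when not supplied).
#' @slot inflationFactor numeric(1), (1 + eta)^-1 (NA when eta absent).
#' @slot expectedEstimate numeric(1), betaGO / ((1 + eta) betaGE).
#'
#' @exportClass MrEstimate
setClass("MrEstimate",
  representation(betaGO = "numeric", betaGE = "numeric",
                 waldRatio = "numeric", eta = "numeric",
                 inflationFactor = "numeric",
                 expectedEstimate = "numeric"))
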