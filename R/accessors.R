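# Constructors, accessors and show methods.

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix, samples x variants, additive dosages in
#'   \[0, 2\].
#' @param variantIds character vector of variant identifiers (defaults to
#'   column names or `snp1..snpm`).
#' @param positions integer vector of 1-based base-pair positions
#'   (defaults to `NA`).
#' @param mafs allele frequencies of the coded allele; computed from the
#'   dosages as `(2 n2 + n1) / (2 N)` when not supplied.
#' @param sampleIds optional sample identifiers.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 2, 1), ncol = 2))
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosages, variantIds = NULL, positions = NULL,
                           mafs = NULL, sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  m <- ncol(dosages)
  if (is.null(variantIds)) {
    variantIds <- colnames(dosages)
    if (is.null(variantIds)) variantIds <- paste0("snp", seq_len(m))
  }
  if (is.null(positions)) positions <- rep(NA_integer_, m)
  if (is.null(mafs)) mafs <- colMeans(dosages) / 2
  if (is.null(sampleIds)) {
    sampleIds <- rownames(dosages)
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(dosages)))
  }
  a <- t(dosages)
  dimnames(a) <- list(variantIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = a),
    rowData = S4Vectors::DataFrame(variant_id = variantIds,
                                   position = as.integer(positions),
                                   maf = as.numeric(mafs)))
  methods::new("GenotypeMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x)
  as.character(SummarizedExperiment::rowData(x)$variant_id))

#' @rdname accessors
#' @export
setMethod("variantPositions", "GenotypeMatrix", function(x)
  SummarizedExperiment::rowData(x)$position)

#' @rdname accessors
#' @export
setMethod("realizedMAF", "GenotypeMatrix", function(x)
  SummarizedExperiment::rowData(x)$maf)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants\n",
              ncol(object), nrow(object)))
  cat("  coded-allele frequency range:",
      paste(signif(range(realizedMAF(object)), 3), collapse = " - "), "\n")
})

#' Construct a CensoredPhenotype
#'
#' @param observed numeric vector of LOD-substituted measurements.
#' @param lod numeric(1), the limit of detection; `-Inf` when uncensored.
#' @param isCensored logical vector; defaults to `observed <= lod`.
#' @param latent optional numeric vector of pre-censoring values
#'   (simulation only).
#' @return a [CensoredPhenotype-class] object.
#' @export
CensoredPhenotype <- function(observed, lod = -Inf,
                              isCensored = observed <= lod,
                              latent = numeric(0)) {
  methods::new("CensoredPhenotype", observed = as.numeric(observed),
               lod = as.numeric(lod), isCensored = as.logical(isCensored),
               latent = as.numeric(latent))
}

#' @rdname accessors
#' @export
setMethod("observedValues", "CensoredPhenotype", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("lodValue", "CensoredPhenotype", function(x) x@lod)

#' @rdname accessors
#' @export
setMethod("isCensored", "CensoredPhenotype", function(x) x@isCensored)

#' @rdname accessors
#' @export
setMethod("latentValues", "CensoredPhenotype", function(x) x@latent)

#' @rdname accessors
#' @export
setMethod("censoredProportion", "CensoredPhenotype", function(x)
  mean(x@isCensored))

setMethod("show", "CensoredPhenotype", function(object) {
  cat(sprintf(
    "CensoredPhenotype: n = %d, LOD = %s, %.1f%% censored%s\n",
    length(object@observed), format(object@lod, digits = 4),
    100 * mean(object@isCensored),
    if (length(object@latent)) " (latent values retained)" else ""))
})

#' @rdname accessors
#' @export
setMethod("transformedValues", "TransformedOutcome", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("tiesPolicy", "TransformedOutcome", function(x) x@tiesPolicy)

#' @rdname accessors
#' @export
setMethod("censorThreshold", "TransformedOutcome", function(x)
  x@censorThreshold)

setMethod("show", "TransformedOutcome", function(object) {
  cat(sprintf(
    "TransformedOutcome: n = %d, ties = '%s', offset = %.3g%s\n",
    length(object@values), object@tiesPolicy, object@offset,
    if (length(object@censorThreshold))
      sprintf(", censor threshold = %.4g", object@censorThreshold) else ""))
})

#' @rdname accessors
#' @export
setMethod("pseudoTime", "CoxOutcome", function(x) x@pseudoTime)

#' @rdname accessors
#' @export
setMethod("eventIndicator", "CoxOutcome", function(x) x@event)

setMethod("show", "CoxOutcome", function(object) {
  cat(sprintf("CoxOutcome: n = %d, %d events (above LOD)\n",
              length(object@pseudoTime), sum(object@event)))
})

#' @rdname accessors
#' @export
setMethod("effectEstimate", "FitResult", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("standardError", "FitResult", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("pValue", "FitResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("isConverged", "FitResult", function(x) x@converged)

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult [%s]: beta = %s, se = %s, p = %s, converged = %s (n = %d)\n",
    object@model, format(object@beta, digits = 5),
    format(object@se, digits = 4), format(object@pValue, digits = 4),
    object@converged, object@nUsed))
  if (!is.null(object@diagnostics$reason))
    cat("  reason:", object@diagnostics$reason, "\n")
})

#' @rdname accessors
#' @export
setMethod("resultTable", "GwasTable", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("gwasMetadata", "GwasTable", function(x) x@metadata)

#' @export
#' @method as.data.frame GwasTable
as.data.frame.GwasTable <- function(x, ...) x@table

setMethod("show", "GwasTable", function(object) {
  tab <- object@table
  cat(sprintf("GwasTable: %d variants, model = %s\n", nrow(tab),
              object@metadata$model %||% "?"))
  if ("clump_id" %in% names(tab))
    cat(sprintf("  %d clumps (%d index variants)\n",
                length(unique(stats::na.omit(tab$clump_id))),
                sum(tab$is_index %in% TRUE)))
  if ("refined_beta" %in% names(tab))
    cat(sprintf("  %d variants Tobit-refined\n",
                sum(!is.na(tab$refined_beta))))
  print(head(tab, 6))
  if (nrow(tab) > 6) cat("  ...\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a SimulationScenario
#'
#' @param nIndividuals sample size N.
#' @param maf minor allele frequency in (0, 0.5].
#' @param effectSize additive effect beta (0 under the null).
#' @param censoredProportion fraction censored, in \[0, 1).
#' @param nSim number of simulation replicates.
#' @param seed master seed for the scenario.
#' @return a [SimulationScenario-class] object.
#' @export
simulationScenario <- function(nIndividuals, maf, effectSize = 0,
                               censoredProportion = 0, nSim = 1L,
                               seed = 1L) {
  methods::new("SimulationScenario",
               nIndividuals = as.integer(nIndividuals),
               maf = as.numeric(maf), effectSize = as.numeric(effectSize),
               censoredProportion = as.numeric(censoredProportion),
               nSim = as.integer(nSim), seed = as.integer(seed))
}

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario: N = %d, MAF = %.3g, beta = %.3g, %.0f%% censored, %d reps (seed %d)\n",
    object@nIndividuals, object@maf, object@effectSize,
    100 * object@censoredProportion, object@nSim, object@seed))
})

#' Construct an LdBlockSpec
#'
#' @param targetR signed genotype-scale correlations with the lead SNP
#'   (the lead carries 1).
#' @param mafs per-variant allele frequencies in (0, 0.5].
#' @param leadIndex position of the lead SNP within the block.
#' @param strategy `"single_causal"` (only the lead carries `leadBeta`) or
#'   `"ld_proportional"` (variant j carries `leadBeta * targetR[j]`).
#' @param leadBeta effect size of the lead SNP.
#' @param positions 1-based base-pair positions (default: 10 kb spacing).
#' @return an [LdBlockSpec-class] object.
#' @export
ldBlockSpec <- function(targetR, mafs, leadIndex = 1L,
                        strategy = c("single_causal", "ld_proportional"),
                        leadBeta = 0.1, positions = NULL) {
  strategy <- match.arg(strategy)
  m <- length(targetR)
  if (length(mafs) == 1L) mafs <- rep(mafs, m)
  if (is.null(positions))
    positions <- as.integer(1e6 + (seq_len(m) - 1L) * 10000L)
  methods::new("LdBlockSpec", leadIndex = as.integer(leadIndex),
               targetR = as.numeric(targetR), mafs = as.numeric(mafs),
               strategy = strategy, leadBeta = as.numeric(leadBeta),
               positions = as.integer(positions))
}

setMethod("show", "LdBlockSpec", function(object) {
  cat(sprintf(
    "LdBlockSpec: %d variants, lead #%d, strategy = %s, lead beta = %.3g\n",
    length(object@targetR), object@leadIndex, object@strategy,
    object@leadBeta))
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("MrEstimate: Wald ratio = %.4g (betaGO %.4g / betaGE %.4g)\n",
              object@waldRatio, object@betaGO, object@betaGE))
  if (!is.na(object@eta))
    cat(sprintf(
      "  attenuation eta = %.4g -> inflation (1+eta)^-1 = %.4g, expected estimate = %.4g\n",
      object@eta, object@inflationFactor, object@expectedEstimate))
})
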