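# The two-step Linear-Tobit GWAS scheme: linear screening across all
# variants, greedy LD clumping of the hits, Tobit refinement of the
# clump index variants.

#' Clumping parameters
#'
#' Thresholds for greedy LD clumping: index variants need `p < p1`,
#' members need `p < p2`, squared dosage correlation with their index
#' `>= r2`, and a base-pair distance within `windowKb` kilobases.
#'
#' @param p1 index significance threshold (default genome-wide 5e-8).
#' @param p2 member inclusion threshold (default 1e-4).
#' @param r2 LD threshold on squared Pearson correlation (default 0.1).
#' @param windowKb window half-width in kb (default 1000).
#' @return a named list of validated parameters.
#' @export
clumpParams <- function(p1 = 5e-8, p2 = 1e-4, r2 = 0.1, windowKb = 1000) {
  if (p1 > p2) stop("p1 must be <= p2")
  if (r2 <= 0 || r2 > 1) stop("r2 must lie in (0, 1]")
  if (windowKb <= 0) stop("windowKb must be positive")
  list(p1 = p1, p2 = p2, r2 = r2, windowKb = windowKb)
}

modelOutcome <- function(phenotype, model, offset = 3 / 8) {
  switch(model,
    linear = prepareLinearOutcome(phenotype, offset),
    tobit = prepareTobitOutcome(phenotype, offset),
    cox = prepareCoxOutcome(phenotype),
    logistic = prepareLogisticOutcome(phenotype),
    stop("unknown model: ", model))
}

fitOne <- function(model, outcome, g, covariates) {
  switch(model,
    linear = fitLinear(outcome, g, covariates),
    tobit = fitTobit(outcome, g, covariates),
    cox = fitCox(outcome, g, covariates),
    logistic = fitLogistic(outcome, g, covariates))
}

#' Single-model GWAS screen across all variants
#'
#' Applies the model's own outcome preprocessing once (rank-INT with the
#' model's tie policy, Cox flip, or detection indicator) and fits every
#' variant. Variants failing preconditions (e.g. minor allele count < 3)
#' are recorded as `NA` rows with a reason, not dropped.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotype a [CensoredPhenotype-class] aligned with the
#'   genotype samples.
#' @param covariates optional numeric covariate matrix.
#' @param model `"linear"`, `"tobit"`, `"cox"` or `"logistic"`.
#' @param intOffset rank-INT offset for the linear/Tobit preparations.
#' @return a [GwasTable-class], sorted by p-value then position.
#' @export
gwasScreen <- function(genotypes, phenotype, covariates = NULL,
                       model = c("linear", "tobit", "cox", "logistic"),
                       intOffset = 3 / 8) {
  model <- match.arg(model)
  stopifnot(methods::is(genotypes, "GenotypeMatrix"),
            methods::is(phenotype, "CensoredPhenotype"))
  d <- dosages(genotypes)
  if (nrow(d) != length(observedValues(phenotype)))
    stop("sample mismatch between genotypes and phenotype")
  outcome <- modelOutcome(phenotype, model, intOffset)
  m <- ncol(d)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    fr <- tryCatch(fitOne(model, outcome, d[, j], covariates),
                   error = function(e)
                     skippedFit(model, nrow(d), conditionMessage(e)))
    rows[[j]] <- data.frame(
      variant_id = variantIds(genotypes)[j],
      position = variantPositions(genotypes)[j],
      maf = realizedMAF(genotypes)[j],
      n = fr@nUsed, model = model, beta = fr@beta, se = fr@se,
      p_value = fr@pValue, converged = fr@converged,
      reason = fr@diagnostics$reason %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$beta))) stop("zero analyzable variants")
  tab <- tab[order(tab$p_value, tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  methods::new("GwasTable", table = tab,
               metadata = list(
                 model = model, int_offset = intOffset,
                 ties_policy = switch(model, linear = "average",
                                      tobit = "max", NA_character_),
                 lod = lodValue(phenotype),
                 censored_proportion = censoredProportion(phenotype)))
}

#' Greedy LD clumping of GWAS hits
#'
#' Repeatedly takes the smallest-p unassigned variant with `p < p1` as a
#' clump index (ties broken by smaller base-pair position) and assigns
#' to it every unassigned variant with `p < p2`, squared dosage
#' correlation `>= r2` with the index, and position within `windowKb` kb.
#' LD is computed from the analysis sample's dosages.
#'
#' @param table a [GwasTable-class] from [gwasScreen()].
#' @param genotypes the [GenotypeMatrix-class] the table was computed
#'   from (for LD).
#' @param params a [clumpParams()] list.
#' @return the table with `clump_id` (NA for unassigned) and `is_index`
#'   columns; zero clumps when nothing passes `p1`.
#' @export
clumpVariants <- function(table, genotypes, params = clumpParams()) {
  stopifnot(methods::is(table, "GwasTable"))
  tab <- table@table
  if (any(is.na(tab$position)))
    stop("clumping requires variant positions")
  d <- dosages(genotypes)
  idx <- match(tab$variant_id, variantIds(genotypes))
  if (anyNA(idx)) stop("table variants missing from genotypes")
  clump <- rep(NA_integer_, nrow(tab))
  isIndex <- rep(FALSE, nrow(tab))
  nextId <- 0L
  repeat {
    cand <- which(is.na(clump) & !is.na(tab$p_value) &
                    tab$p_value < params$p1)
    if (!length(cand)) break
    cand <- cand[order(tab$p_value[cand], tab$position[cand])]
    i <- cand[1]
    nextId <- nextId + 1L
    clump[i] <- nextId
    isIndex[i] <- TRUE
    open <- which(is.na(clump) & !is.na(tab$p_value) &
                    tab$p_value < params$p2 &
                    abs(tab$position - tab$position[i]) <=
                      params$windowKb * 1000)
    if (length(open)) {
      r <- drop(stats::cor(d[, idx[i]], d[, idx[open], drop = FALSE]))
      clump[open[r^2 >= params$r2]] <- nextId
    }
  }
  tab$clump_id <- clump
  tab$is_index <- isIndex
  methods::new("GwasTable", table = tab,
               metadata = c(table@metadata, list(clump_params = params)))
}

#' Tobit refinement of selected variants
#'
#' Refits the selected variants (clump index variants by default) with
#' the Tobit engine on the max-tie rank-INT outcome, populating
#' `refined_beta`, `refined_se`, `refined_p` and `refined_converged`
#' while leaving the screening columns untouched. Non-convergence is
#' recorded per variant, not fatal.
#'
#' @param table a [GwasTable-class] (clumped, unless `variants` given).
#' @param genotypes the [GenotypeMatrix-class].
#' @param phenotype the [CensoredPhenotype-class].
#' @param covariates optional covariate matrix.
#' @param variants optional character vector of variant ids to refine
#'   instead of the clump index variants.
#' @param refineAll when `TRUE`, refine every variant with screening
#'   `p < p1` (5e-8 unless clump params say otherwise).
#' @param intOffset rank-INT offset.
#' @return the table with refinement columns; unchanged (plus empty
#'   columns) when the selection is empty.
#' @export
refineTobit <- function(table, genotypes, phenotype, covariates = NULL,
                        variants = NULL, refineAll = FALSE,
                        intOffset = 3 / 8) {
  stopifnot(methods::is(table, "GwasTable"))
  tab <- table@table
  sel <- if (!is.null(variants)) {
    which(tab$variant_id %in% variants)
  } else if (refineAll) {
    p1 <- (table@metadata$clump_params %||% clumpParams())$p1
    which(!is.na(tab$p_value) & tab$p_value < p1)
  } else {
    if (is.null(tab$is_index))
      stop("no clump assignments; run clumpVariants() or give `variants`")
    which(tab$is_index)
  }
  tab$refined_beta <- NA_real_
  tab$refined_se <- NA_real_
  tab$refined_p <- NA_real_
  tab$refined_converged <- NA
  if (length(sel)) {
    outcome <- prepareTobitOutcome(phenotype, intOffset)
    d <- dosages(genotypes)
    idx <- match(tab$variant_id, variantIds(genotypes))
    for (i in sel) {
      fr <- tryCatch(fitTobit(outcome, d[, idx[i]], covariates),
                     error = function(e)
                       skippedFit("tobit", nrow(d), conditionMessage(e)))
      tab$refined_beta[i] <- fr@beta
      tab$refined_se[i] <- fr@se
      tab$refined_p[i] <- fr@pValue
      tab$refined_converged[i] <- fr@converged
    }
  }
  methods::new("GwasTable", table = tab,
               metadata = c(table@metadata,
                            list(n_tobit_fits = length(sel))))
}

#' The two-step Linear-Tobit GWAS scheme
#'
#' Composition of [gwasScreen()] with the linear model (fast, applied to
#' every variant), [clumpVariants()] to extract independent lead
#' variants, and [refineTobit()] to replace the attenuated linear effect
#' estimates of the leads with Tobit estimates. The Tobit cost is
#' proportional to the number of leads only; `gwasMetadata()$n_tobit_fits`
#' records how many censored-likelihood fits were run.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotype a [CensoredPhenotype-class].
#' @param covariates optional covariate matrix (used identically in both
#'   steps).
#' @param params a [clumpParams()] list.
#' @param refineAll refine all `p < p1` variants instead of clump leads.
#' @param intOffset rank-INT offset.
#' @return a [GwasTable-class] with screening, clump and refinement
#'   columns.
#' @export
linearTobitScheme <- function(genotypes, phenotype, covariates = NULL,
                              params = clumpParams(), refineAll = FALSE,
                              intOffset = 3 / 8) {
  screened <- gwasScreen(genotypes, phenotype, covariates, "linear",
                         intOffset)
  clumped <- clumpVariants(screened, genotypes, params)
  refineTobit(clumped, genotypes, phenotype, covariates,
              refineAll = refineAll, intOffset = intOffset)
}
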