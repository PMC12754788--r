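# Censoring-aware outcome preprocessing: rank-based inverse normal
# transformation with tie policies, the Cox left-to-right flip, and the
# detection indicator for logistic regression.

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles `qnorm((r - k) / (n - 2k + 1))` with
#' ranks `r` assigned under the chosen tie policy and offset `k` (Blom's
#' 3/8 by default, so the denominator is n + 1/4). `"average"` gives tied
#' values the central rank of their group; `"max"` gives them the largest
#' rank, which is the convention used to place a censored block at the
#' transformed-scale detection limit for the Tobit fit.
#'
#' @param values numeric vector (n >= 2, at least two distinct values).
#' @param tiesPolicy `"average"` or `"max"`.
#' @param offset rank offset k in (0, 0.5\]; default 3/8.
#' @return a [TransformedOutcome-class] (no censor threshold set).
#' @examples
#' transformedValues(rankInverseNormal(c(1, 2, 3)))
#' @export
rankInverseNormal <- function(values, tiesPolicy = c("average", "max"),
                              offset = 3 / 8) {
  tiesPolicy <- match.arg(tiesPolicy)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (any(is.na(values))) stop("values must not contain NA")
  if (length(unique(values)) < 2)
    stop("all values identical: rank transform undefined")
  r <- rank(values, ties.method = tiesPolicy)
  out <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  methods::new("TransformedOutcome", values = out, tiesPolicy = tiesPolicy,
               offset = offset, censorThreshold = numeric(0))
}

#' Prepare the outcome for linear-model screening
#'
#' Rank-based inverse normal transform of the full substituted vector
#' with the `"average"` tie policy, so every censored observation (tied
#' at the LOD) is imputed with the average rank of the censored block.
#'
#' @param ph a [CensoredPhenotype-class].
#' @param offset rank offset k; default 3/8.
#' @return a [TransformedOutcome-class] without a censor threshold.
#' @export
prepareLinearOutcome <- function(ph, offset = 3 / 8) {
  stopifnot(methods::is(ph, "CensoredPhenotype"))
  rankInverseNormal(observedValues(ph), "average", offset)
}

#' Prepare the outcome for the Tobit fit
#'
#' Rank-based inverse normal transform with the `"max"` tie policy, so
#' all censored observations share the largest rank of their tied block
#' and map to a single transformed value; that value is recorded as the
#' transformed-scale censoring threshold passed to the Tobit likelihood.
#' With no censored observations the threshold is placed below the
#' smallest transformed value, and the Tobit fit reduces to the
#' uncensored maximum likelihood (= OLS) solution.
#'
#' @param ph a [CensoredPhenotype-class] with at least one uncensored
#'   observation.
#' @param offset rank offset k; default 3/8.
#' @return a [TransformedOutcome-class] with `censorThreshold()` set.
#' @export
prepareTobitOutcome <- function(ph, offset = 3 / 8) {
  stopifnot(methods::is(ph, "CensoredPhenotype"))
  to <- rankInverseNormal(observedValues(ph), "max", offset)
  cen <- isCensored(ph)
  thr <- if (any(cen)) to@values[cen][1] else min(to@values) - 1
  methods::new("TransformedOutcome", values = to@values,
               tiesPolicy = "max", offset = offset,
               censorThreshold = thr)
}

#' Flip a left-censored phenotype onto a right-censored pseudo-time scale
#'
#' `pseudoTime_i = max(observed) - observed_i`, with above-LOD
#' measurements treated as events (`delta_i = I(observed_i > LOD)`). No
#' rank transformation is applied; the Cox partial likelihood only uses
#' the ordering.
#'
#' @param ph a [CensoredPhenotype-class] (n >= 2).
#' @return a [CoxOutcome-class].
#' @export
prepareCoxOutcome <- function(ph) {
  stopifnot(methods::is(ph, "CensoredPhenotype"))
  y <- observedValues(ph)
  if (length(y) < 2) stop("need at least 2 observations")
  methods::new("CoxOutcome", pseudoTime = max(y) - y,
               event = y > lodValue(ph))
}

#' Detection indicator for logistic regression
#'
#' `delta_i = 1` when the observation lies above the LOD, 0 when
#' censored. Errors when only one class is present (the logistic model is
#' undefined).
#'
#' @param ph a [CensoredPhenotype-class].
#' @return logical vector of detection indicators.
#' @export
prepareLogisticOutcome <- function(ph) {
  stopifnot(methods::is(ph, "CensoredPhenotype"))
  delta <- observedValues(ph) > lodValue(ph)
  if (all(delta) || !any(delta))
    stop("single-class outcome: logistic model undefined without both ",
         "below- and above-LOD observations")
  delta
}
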