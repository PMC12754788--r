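# The four regression engines. The linear screen uses a direct QR
# least-squares fit; the Tobit engine maximizes the left-censored
# Gaussian likelihood with an analytic gradient; Cox goes through
# survival::coxph; logistic through stats::glm.fit.

minorAlleleCount <- function(g) min(sum(g), sum(2 - g))

# Intercept + genotype (+ covariates) design; genotype is column 2.
buildDesign <- function(genotype, covariates = NULL, n = length(genotype)) {
  if (length(genotype) != n) stop("genotype length mismatch")
  X <- cbind(`(Intercept)` = 1, g = as.numeric(genotype))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariate row mismatch")
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  X
}

skippedFit <- function(model, n, reason) {
  methods::new("FitResult", model = model, beta = NA_real_, se = NA_real_,
               pValue = NA_real_, sigma = NA_real_, converged = FALSE,
               nUsed = as.integer(n), diagnostics = list(reason = reason))
}

outcomeVector <- function(outcome) {
  if (methods::is(outcome, "TransformedOutcome")) outcome@values
  else as.numeric(outcome)
}

# QR least squares with genotype-coefficient Wald/t test.
olsCore <- function(X, y) {
  qrx <- qr(X)
  coefs <- qr.coef(qrx, y)
  res <- y - drop(X %*% coefs)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtxinv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot),
                                drop = FALSE]
  se <- sqrt(diag(xtxinv) * sigma2)
  list(coef = coefs, se = se, df = df, sigma = sqrt(sigma2))
}

#' Linear-model association test
#'
#' Ordinary least squares of the (typically rank-transformed) outcome on
#' intercept + genotype dosage + optional covariates, with a two-sided
#' t-test on the genotype coefficient. Variants with minor allele count
#' below 3 are skipped with an `NA` result rather than an error, so
#' genome-wide loops survive monomorphic columns.
#'
#' @param outcome a [TransformedOutcome-class] or numeric vector.
#' @param genotype dosage vector.
#' @param covariates optional numeric matrix of covariates.
#' @return a [FitResult-class] with `model = "linear"`.
#' @export
fitLinear <- function(outcome, genotype, covariates = NULL) {
  y <- outcomeVector(outcome)
  n <- length(y)
  if (minorAlleleCount(genotype) < 3)
    return(skippedFit("linear", n, "minor allele count < 3"))
  X <- buildDesign(genotype, covariates, n)
  if (n <= ncol(X)) stop("more parameters than observations")
  fit <- olsCore(X, y)
  tstat <- fit$coef[2] / fit$se[2]
  p <- 2 * stats::pt(-abs(tstat), fit$df)
  methods::new("FitResult", model = "linear", beta = unname(fit$coef[2]),
               se = unname(fit$se[2]), pValue = max(p, .Machine$double.xmin),
               sigma = fit$sigma, converged = TRUE, nUsed = as.integer(n),
               diagnostics = list())
}

# Stable inverse Mills ratio phi(z)/Phi(z).
millsRatio <- function(z)
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))

# Left-censored Gaussian log-likelihood in Olsen's reparameterization
# theta = (gamma, h) with gamma = beta / sigma, h = 1 / sigma, in which
# the likelihood is globally concave: uncensored rows contribute
# log h + log phi(h y - x'gamma), censored rows log Phi(h c - x'gamma).
tobitLogLik <- function(theta, Xu, yu, Xc, cthr) {
  k <- ncol(Xu)
  gam <- theta[seq_len(k)]
  h <- theta[k + 1]
  if (h <= 0) return(-Inf)
  ru <- h * yu - drop(Xu %*% gam)
  ll <- length(yu) * log(h) + sum(stats::dnorm(ru, log = TRUE))
  if (nrow(Xc))
    ll <- ll + sum(stats::pnorm(h * cthr - drop(Xc %*% gam),
                                log.p = TRUE))
  ll
}

tobitScoreHess <- function(theta, Xu, yu, Xc, cthr, XtXu, Xty, Syy) {
  k <- ncol(Xu)
  gam <- theta[seq_len(k)]
  h <- theta[k + 1]
  nu <- length(yu)
  ru <- h * yu - drop(Xu %*% gam)
  ggam <- drop(crossprod(Xu, ru))
  gh <- nu / h - sum(ru * yu)
  Hgg <- -XtXu
  Hgh <- Xty
  Hhh <- -nu / h^2 - Syy
  if (nrow(Xc)) {
    zc <- h * cthr - drop(Xc %*% gam)
    lam <- millsRatio(zc)
    w <- lam * (zc + lam)
    ggam <- ggam - drop(crossprod(Xc, lam))
    gh <- gh + cthr * sum(lam)
    Hgg <- Hgg - crossprod(Xc, Xc * w)
    Hgh <- Hgh + cthr * drop(crossprod(Xc, w))
    Hhh <- Hhh - cthr^2 * sum(w)
  }
  H <- rbind(cbind(Hgg, Hgh), c(Hgh, Hhh))
  list(grad = c(ggam, gh), hess = H)
}

#' Tobit (left-censored Gaussian) association test
#'
#' Maximizes the censored-normal likelihood: uncensored observations
#' contribute the Gaussian density, censored ones the probability
#' `Phi((c - x'beta)/sigma)` of lying at or below the transformed-scale
#' threshold `c` carried by the outcome (see [prepareTobitOutcome()]).
#' The likelihood is maximized by damped Newton iteration with analytic
#' gradient and Hessian in Olsen's reparameterization
#' `(gamma, h) = (beta / sigma, 1 / sigma)`, in which it is globally
#' concave, from an OLS warm start; a BFGS restart is tried before
#' declaring non-convergence (per-observation gradient norm below 1e-6).
#' With no censored observations the maximum likelihood solution is the
#' OLS fit and is returned directly.
#'
#' @param outcome a [TransformedOutcome-class] with `censorThreshold()`
#'   set (from [prepareTobitOutcome()]).
#' @param genotype dosage vector.
#' @param covariates optional numeric matrix of covariates.
#' @param maxit maximum BFGS iterations.
#' @return a [FitResult-class] with `model = "tobit"`; `sigma` is the
#'   residual-scale estimate and `diagnostics` records the gradient norm.
#' @export
fitTobit <- function(outcome, genotype, covariates = NULL, maxit = 200L) {
  stopifnot(methods::is(outcome, "TransformedOutcome"))
  if (!length(outcome@censorThreshold))
    stop("outcome carries no censorThreshold; use prepareTobitOutcome()")
  y <- outcome@values
  n <- length(y)
  if (minorAlleleCount(genotype) < 3)
    return(skippedFit("tobit", n, "minor allele count < 3"))
  cthr <- outcome@censorThreshold
  cen <- y <= cthr + 1e-12
  if (all(cen)) stop("all observations censored")
  X <- buildDesign(genotype, covariates, n)
  k <- ncol(X)
  if (!any(cen)) {
    # Uncensored limit: the censored likelihood reduces to the Gaussian
    # one, whose MLE is OLS with sigma^2 = RSS / n.
    fit <- olsCore(X, y)
    res <- y - drop(X %*% fit$coef)
    z <- fit$coef[2] / fit$se[2]
    return(methods::new("FitResult", model = "tobit",
                        beta = unname(fit$coef[2]), se = unname(fit$se[2]),
                        pValue = max(2 * stats::pnorm(-abs(z)),
                                     .Machine$double.xmin),
                        sigma = sqrt(mean(res^2)), converged = TRUE,
                        nUsed = as.integer(n),
                        diagnostics = list(nCensored = 0L)))
  }
  ols <- olsCore(X, y)
  Xu <- X[!cen, , drop = FALSE]
  yu <- y[!cen]
  Xc <- X[cen, , drop = FALSE]
  XtXu <- crossprod(Xu)
  Xty <- drop(crossprod(Xu, yu))
  Syy <- sum(yu^2)
  s0 <- max(ols$sigma, 1e-3)
  theta <- c(ols$coef / s0, 1 / s0)
  ll <- tobitLogLik(theta, Xu, yu, Xc, cthr)
  iter <- 0L
  gnorm <- Inf
  while (iter < maxit) {
    iter <- iter + 1L
    sh <- tobitScoreHess(theta, Xu, yu, Xc, cthr, XtXu, Xty, Syy)
    gnorm <- max(abs(sh$grad)) / n
    if (gnorm < 1e-9) break
    step <- tryCatch(solve(sh$hess, sh$grad), error = function(e) NULL)
    if (is.null(step)) break
    # Damped ascent: halve until the likelihood does not decrease and
    # the precision parameter h stays positive.
    damp <- 1
    repeat {
      cand <- theta - damp * step
      llc <- if (cand[k + 1] > 0)
        tobitLogLik(cand, Xu, yu, Xc, cthr) else -Inf
      if (llc >= ll - 1e-10 || damp < 1e-8) break
      damp <- damp / 2
    }
    if (!is.finite(llc) || llc < ll - 1e-10) break
    moved <- max(abs(cand - theta))
    theta <- cand
    ll <- llc
    if (moved < 1e-12) break
  }
  sh <- tobitScoreHess(theta, Xu, yu, Xc, cthr, XtXu, Xty, Syy)
  gnorm <- max(abs(sh$grad)) / n
  converged <- is.finite(gnorm) && gnorm < 1e-6
  if (!converged) {
    # Quasi-Newton restart on the same concave surface.
    opt <- tryCatch(stats::optim(
      theta, function(p) -tobitLogLik(p, Xu, yu, Xc, cthr),
      function(p) -tobitScoreHess(p, Xu, yu, Xc, cthr, XtXu, Xty,
                                  Syy)$grad,
      method = "BFGS", control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value >= ll) theta <- opt$par
    sh <- tobitScoreHess(theta, Xu, yu, Xc, cthr, XtXu, Xty, Syy)
    gnorm <- max(abs(sh$grad)) / n
    converged <- is.finite(gnorm) && gnorm < 1e-6
  }
  gam <- theta[seq_len(k)]
  h <- theta[k + 1]
  beta <- gam[2] / h
  vc <- tryCatch(solve(-sh$hess), error = function(e) NULL)
  se <- NA_real_
  if (!is.null(vc)) {
    # Delta method back to beta = gamma / h.
    jac <- numeric(k + 1)
    jac[2] <- 1 / h
    jac[k + 1] <- -gam[2] / h^2
    v <- drop(t(jac) %*% vc %*% jac)
    if (is.finite(v) && v > 0) se <- sqrt(v)
  }
  z <- beta / se
  methods::new("FitResult", model = "tobit", beta = unname(beta),
               se = unname(se),
               pValue = if (is.na(se)) NA_real_
                        else max(2 * stats::pnorm(-abs(z)),
                                 .Machine$double.xmin),
               sigma = 1 / h, converged = converged,
               nUsed = as.integer(n),
               diagnostics = list(nCensored = sum(cen),
                                  gradientNorm = gnorm,
                                  iterations = iter))
}

#' Cox proportional hazards association test on the flipped scale
#'
#' Fits `h(t | g) = h0(t) exp(beta * g)` on the flipped pseudo-time with
#' above-LOD measurements as events, via the Efron-corrected partial
#' likelihood ([survival::coxph()]). The censored block is tied at the
#' largest pseudo-time but consists of non-events, so event-time ties do
#' not arise with continuous phenotypes.
#'
#' @param outcome a [CoxOutcome-class].
#' @param genotype dosage vector.
#' @param covariates optional numeric matrix of covariates.
#' @return a [FitResult-class] with `model = "cox"`; the underlying
#'   `coxph` fit is kept in `diagnostics$coxFit` for the Schoenfeld test.
#' @export
fitCox <- function(outcome, genotype, covariates = NULL) {
  stopifnot(methods::is(outcome, "CoxOutcome"))
  n <- length(outcome@pseudoTime)
  if (!any(outcome@event)) stop("no events (no above-LOD observations)")
  if (minorAlleleCount(genotype) < 3)
    return(skippedFit("cox", n, "minor allele count < 3"))
  X <- buildDesign(genotype, covariates, n)
  dat <- data.frame(.time = outcome@pseudoTime, .event = outcome@event,
                    X[, -1, drop = FALSE], check.names = FALSE)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  monotone <- any(grepl("infinite|did not converge|beta may be infinite",
                        warn, ignore.case = TRUE))
  beta <- unname(stats::coef(fit)["g"])
  se <- sqrt(diag(fit$var))[match("g", names(stats::coef(fit)))]
  z <- beta / se
  methods::new("FitResult", model = "cox", beta = beta, se = unname(se),
               pValue = max(2 * stats::pnorm(-abs(z)),
                            .Machine$double.xmin),
               sigma = NA_real_, converged = !monotone,
               nUsed = as.integer(n),
               diagnostics = list(coxFit = fit, nEvents = sum(outcome@event),
                                  warnings = warn))
}

#' Schoenfeld residuals test of the proportional hazards assumption
#'
#' Grambsch-Therneau score test for correlation between the scaled
#' Schoenfeld residuals of the genotype term and transformed pseudo-time
#' ([survival::cox.zph()]); small p-values indicate that the hazard
#' associated with the genotype is not constant along the flipped
#' biomarker scale, i.e. the PH assumption fails. Conventional
#' thresholds for flagging a violation are 0.05 and the genome-wide
#' 5e-8.
#'
#' @param fit a converged [FitResult-class] from [fitCox()].
#' @param transform time transform passed to `cox.zph` (`"km"` default,
#'   or `"identity"`).
#' @return the p-value of the genotype term's PH test.
#' @export
schoenfeldPHTest <- function(fit, transform = c("km", "identity")) {
  transform <- match.arg(transform)
  stopifnot(methods::is(fit, "FitResult"), fit@model == "cox")
  if (!fit@converged) stop("requires a converged Cox fit")
  if (is.null(fit@diagnostics$coxFit))
    stop("FitResult carries no coxph fit")
  if (fit@diagnostics$nEvents < 2)
    stop("Schoenfeld test undefined with fewer than 2 events")
  zph <- survival::cox.zph(fit@diagnostics$coxFit, transform = transform,
                           global = FALSE)
  unname(zph$table["g", "p"])
}

#' Logistic association test on the detection indicator
#'
#' Maximum likelihood logistic regression (IRLS via [stats::glm.fit()])
#' of `I(observed > LOD)` on intercept + genotype + covariates; the
#' genotype coefficient is the log odds of detection per coded allele.
#' Fits with a minority class below 10 observations are refused with a
#' diagnostic rather than returning unstable estimates; complete or
#' quasi-separation is flagged as non-convergence.
#'
#' @param event logical detection indicator (from
#'   [prepareLogisticOutcome()]).
#' @param genotype dosage vector.
#' @param covariates optional numeric matrix of covariates.
#' @return a [FitResult-class] with `model = "logistic"`.
#' @export
fitLogistic <- function(event, genotype, covariates = NULL) {
  event <- as.logical(event)
  n <- length(event)
  if (all(event) || !any(event))
    stop("single-class outcome: logistic model undefined")
  if (min(sum(event), sum(!event)) < 10)
    return(skippedFit("logistic", n, "minority class < 10 observations"))
  if (minorAlleleCount(genotype) < 3)
    return(skippedFit("logistic", n, "minor allele count < 3"))
  X <- buildDesign(genotype, covariates, n)
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(event), family = stats::binomial()))
  p1 <- seq_len(fit$qr$rank)
  vc <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(diag(vc))
  beta <- unname(fit$coefficients[2])
  separated <- !fit$converged || fit$boundary || abs(beta) > 15 ||
    se[2] > 100
  z <- beta / se[2]
  methods::new("FitResult", model = "logistic", beta = beta,
               se = unname(se[2]),
               pValue = max(2 * stats::pnorm(-abs(z)),
                            .Machine$double.xmin),
               sigma = NA_real_, converged = !separated,
               nUsed = as.integer(n),
               diagnostics = if (separated)
                 list(reason = "possible separation") else list())
}
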