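# Independent oracles and small fixture builders shared across tests.

# Brute-force maximization of the left-censored Gaussian likelihood over
# (b0, b1, sigma) by iterative grid refinement; independent of the
# package's Newton solver.
tobitGridOracle <- function(y, g, cthr, rounds = 6, width = c(2, 2, 0.95)) {
  cen <- y <= cthr + 1e-12
  ll <- function(b0, b1, s) {
    mu <- b0 + b1 * g
    sum(dnorm((y[!cen] - mu[!cen]) / s, log = TRUE)) -
      sum(!cen) * log(s) +
      sum(pnorm((cthr - mu[cen]) / s, log.p = TRUE))
  }
  ctr <- c(0, 0, 1)
  for (r in seq_len(rounds)) {
    b0s <- ctr[1] + seq(-width[1], width[1], length.out = 21)
    b1s <- ctr[2] + seq(-width[2], width[2], length.out = 21)
    sgs <- pmax(0.05, ctr[3] + seq(-width[3], width[3], length.out = 21))
    best <- c(NA, NA, NA)
    bestll <- -Inf
    for (b0 in b0s) for (b1 in b1s) for (s in sgs) {
      v <- ll(b0, b1, s)
      if (v > bestll) {
        bestll <- v
        best <- c(b0, b1, s)
      }
    }
    ctr <- best
    width <- width * 2.2 / 20
  }
  list(b0 = ctr[1], b1 = ctr[2], sigma = ctr[3], logLik = bestll)
}

# Cox partial log-likelihood with explicit risk sets (valid when event
# times are distinct, so tie corrections play no role).
coxPartialLogLik <- function(beta, time, event, g) {
  s <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    s <- s + beta * g[i] - log(sum(exp(beta * g[risk])))
  }
  s
}

coxOracle <- function(time, event, g) {
  stats::optimize(coxPartialLogLik, c(-20, 20), maximum = TRUE,
                  tol = 1e-10, time = time, event = event, g = g)$maximum
}

# Exhaustive greedy clumping, written independently of the package:
# scan for the global minimum-p unassigned variant passing p1, then test
# every unassigned variant against the three inclusion conditions.
clumpOracle <- function(p, pos, dos, p1, p2, r2, windowKb) {
  m <- length(p)
  clump <- rep(NA_integer_, m)
  cid <- 0L
  repeat {
    best <- NA_integer_
    for (i in seq_len(m)) {
      if (!is.na(clump[i]) || is.na(p[i]) || p[i] >= p1) next
      if (is.na(best) || p[i] < p[best] ||
          (p[i] == p[best] && pos[i] < pos[best])) best <- i
    }
    if (is.na(best)) break
    cid <- cid + 1L
    clump[best] <- cid
    for (j in seq_len(m)) {
      if (!is.na(clump[j]) || is.na(p[j])) next
      if (p[j] >= p2) next
      if (abs(pos[j] - pos[best]) > windowKb * 1000) next
      if (cor(dos[, j], dos[, best])^2 < r2) next
      clump[j] <- cid
    }
  }
  clump
}

# Single-SNP censored dataset used throughout.
makeCensored <- function(n, beta, maf, cens, seed) {
  set.seed(seed)
  g <- rbinom(n, 2, maf)
  y <- beta * g + rnorm(n)
  list(g = as.numeric(g), ph = applyCensoring(y, cens))
}

# GwasTable straight from raw columns (for clumping tests).
makeTable <- function(variant_id, position, p_value, maf = 0.3) {
  tab <- data.frame(variant_id = variant_id, position = position,
                    maf = maf, n = 100L, model = "linear",
                    beta = 0.1, se = 0.02, p_value = p_value,
                    converged = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  methods::new("GwasTable", table = tab, metadata = list(model = "linear"))
}
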