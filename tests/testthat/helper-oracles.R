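# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written by the most direct route available
# (dense linear algebra, full enumeration, textbook formulas) so it shares
# no code path with the package implementations it checks.

# Brute-force Hardy-Weinberg exact test: enumerate every genotype
# configuration (nAA', nAa', naa') compatible with the observed allele
# counts, weight by the multinomial coefficient times 2^het, and sum the
# probabilities of configurations no more probable than the observed one.
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- Filter(function(h) {
    (nA - h) %% 2 == 0 && (nA - h) >= 0 && (n - h - (nA - h) / 2) >= 0
  }, 0:n)
  logw <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Dense REML log-likelihood computed straight from V = s2u*G + s2e*I via a
# Cholesky factor; no eigen-rotation, no profiling.
denseREMLLogLik <- function(y, X, G, s2u, s2e) {
  n <- length(y)
  V <- s2u * G + s2e * diag(n)
  ch <- chol(V)
  ldV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chX <- chol(XtViX)
  beta <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * ((n - ncol(X)) * log(2 * pi) + ldV + 2 * sum(log(diag(chX))) +
            sum(r * Vi_r))
}

# Textbook Welch two-sample t-test.
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Ordinary least squares by the normal equations.
olsResidOracle <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  unname(drop(y - X %*% beta))
}

# Small simulated data set shared by many tests.
smallSim <- function(n = 200, m = 1500, nQtl = 100, h2 = c(0.3, 0.3, 0.3),
                     rg = 0.8, seed = 11, ...) {
  cfg <- simParams(nIndividuals = n, nMarkers = m, nQtl = nQtl, h2 = h2,
                   geneticCorr = rg, seed = seed, ...)
  g <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(g, cfg)
  list(cfg = cfg, g = g, pheno = sim$phenotypes, tv = sim$trueValues,
       grm = vanRadenGRM(g))
}
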