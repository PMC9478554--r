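# The univariate fits here run on small simulated panels; the dense-V
# oracle in helper-oracles.R is the independent route used throughout.

test_that("eigen-rotated REML log-likelihood equals the dense computation", {
  sim <- smallSim(n = 80, m = 500, nQtl = 40, seed = 25)
  p <- sim$pheno
  y <- traitValues(p, "trait")[, "140"]
  X <- cbind(`(Intercept)` = 1, sexM = as.numeric(p@sex == "M"),
             model.matrix(~ batch - 1, data.frame(batch = p@batch))[, -1])
  G <- grmMatrix(sim$grm)
  set.seed(1)
  for (k in 1:25) {
    s2u <- runif(1, 0.05, 3)
    s2e <- runif(1, 0.05, 3)
    expect_equal(uvREMLLogLik(sim$grm, p, "trait", 140, s2u, s2e),
                 denseREMLLogLik(y, X, G, s2u, s2e), tolerance = 1e-8)
  }
})

test_that("the univariate fit beats a dense brute-force grid", {
  sim <- smallSim(n = 120, m = 800, nQtl = 60, seed = 33)
  fit <- fitUvLMM(sim$grm, sim$pheno, "trait", 210)
  p <- sim$pheno
  y <- traitValues(p, "trait")[, "210"]
  X <- cbind(1, as.numeric(p@sex == "M"),
             model.matrix(~ batch - 1, data.frame(batch = p@batch))[, -1])
  G <- grmMatrix(sim$grm)
  vy <- var(y)
  lams <- exp(seq(log(1e-4), log(1e4), length.out = 25))
  vps <- vy * seq(0.25, 3, length.out = 25)
  best <- -Inf
  for (lam in lams) for (vp in vps) {
    ll <- denseREMLLogLik(y, X, G, vp * lam / (1 + lam), vp / (1 + lam))
    best <- max(best, ll)
  }
  expect_gte(logLikREML(fit), best - 1e-6)
  # and the reported h2 is the arithmetic identity of the components
  vc <- varComponents(fit)
  expect_equal(heritability(fit),
               vc["sigma2u"] / (vc["sigma2u"] + vc["sigma2e"]),
               ignore_attr = TRUE)
})

test_that("GEBVs equal the matched SNP-BLUP ridge oracle", {
  sim <- smallSim(n = 200, m = 1000, nQtl = 80, seed = 41)
  fit <- fitUvLMM(sim$grm, sim$pheno, "trait", 140)
  p <- sim$pheno
  y <- traitValues(p, "trait")[, "140"]
  X <- cbind(1, as.numeric(p@sex == "M"),
             model.matrix(~ batch - 1, data.frame(batch = p@batch))[, -1])
  # ridge marker-effects model with per-marker variance s2u/denom
  af <- alleleFreq(sim$g)
  W <- sweep(dosages(sim$g), 2, 2 * af)
  s2u <- fit@sigma2u; s2e <- fit@sigma2e
  V <- s2u * tcrossprod(W) / sim$grm@denom + s2e * diag(length(y))
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  aHat <- (s2u / sim$grm@denom) * crossprod(W, solve(V, y - X %*% beta))
  expect_equal(unname(gebv(fit)), unname(drop(W %*% aHat)),
               tolerance = 1e-6)
})

test_that("predictGEBV reproduces stored GEBVs and respects no-information", {
  sim <- smallSim(n = 150, m = 600, nQtl = 50, seed = 55)
  ids <- individualIds(sim$g)
  # leave 20 animals unphenotyped
  p <- maskRecords(sim$pheno, ids[1:20], "trait", 1:3)
  fit <- fitUvLMM(sim$grm, p, "trait", 140)
  expect_equal(predictGEBV(fit, sim$grm, fit@phenIds),
               gebv(fit)[fit@phenIds], tolerance = 1e-12)
  expect_equal(predictGEBV(fit, sim$grm, ids[1:20]), gebv(fit)[ids[1:20]],
               tolerance = 1e-12)
  expect_error(predictGEBV(fit, sim$grm, "ghost"), "unknown ids")
  # a genomically unrelated animal has GEBV exactly 0
  G <- grmMatrix(sim$grm)
  n <- nrow(G)
  G2 <- rbind(cbind(G, 0), 0)
  G2[n + 1, n + 1] <- 1
  dimnames(G2) <- list(c(ids, "loner"), c(ids, "loner"))
  grm2 <- new("GRM", mat = G2, nMarkersUsed = sim$grm@nMarkersUsed,
              denom = sim$grm@denom)
  fit2 <- fitUvLMM(grm2, p, "trait", 140)
  expect_equal(unname(gebv(fit2)["loner"]), 0)
  mfit2 <- fitMvLMM(grm2, p, "trait", tol = 1e-6)
  expect_equal(unname(gebv(mfit2)["loner", ]), rep(0, 3))
})

test_that("adding a constant to the records moves only the intercept", {
  sim <- smallSim(n = 120, m = 500, nQtl = 40, seed = 61)
  fit1 <- fitUvLMM(sim$grm, sim$pheno, "trait", 70)
  p2 <- sim$pheno
  v <- p2@values; v[, "trait_70"] <- v[, "trait_70"] + 5
  p2 <- PhenotypeTable(p2@ids, p2@sex, p2@batch, v)
  fit2 <- fitUvLMM(sim$grm, p2, "trait", 70)
  # equality is limited by the Brent search precision on log-lambda
  expect_equal(varComponents(fit1), varComponents(fit2), tolerance = 1e-6)
  expect_equal(gebv(fit1), gebv(fit2), tolerance = 1e-6)
  expect_equal(fit2@beta["(Intercept)"] - fit1@beta["(Intercept)"], 5,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit1@beta[-1], fit2@beta[-1], tolerance = 1e-8)
})

test_that("a pure-noise trait is estimated at the h2 = 0 boundary", {
  sim <- smallSim(n = 300, m = 2000, nQtl = 50, seed = 71)
  h2s <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    v <- sim$pheno@values
    v[, ] <- rnorm(length(v))
    p <- PhenotypeTable(sim$pheno@ids, sim$pheno@sex, sim$pheno@batch, v)
    heritability(fitUvLMM(sim$grm, p, "trait", 140))
  }, numeric(1))
  expect_lt(median(h2s), 0.05)
})

test_that("delta-method SEs are calibrated against the replicate spread", {
  # one genotype panel, many phenotype draws at h2 = 0.3
  cfg0 <- simParams(nIndividuals = 300, nMarkers = 2000, nQtl = 100,
                    h2 = c(0.3, 0.3, 0.3), seed = 77)
  g <- simulateGenotypes(cfg0)
  grm <- vanRadenGRM(g)
  res <- vapply(1:200, function(s) {
    cfg <- simParams(nIndividuals = 300, nMarkers = 2000, nQtl = 100,
                     h2 = c(0.3, 0.3, 0.3), seed = 77 + s)
    sim <- simulatePhenotypes(g, cfg)
    fit <- fitUvLMM(grm, sim$phenotypes, "trait", 140)
    c(fit@h2, fit@seH2)
  }, numeric(2))
  empSD <- sd(res[1, ])
  meanSE <- mean(res[2, ], na.rm = TRUE)
  expect_lt(abs(empSD - meanSE) / meanSE, 0.30)
})

test_that("multivariate EM burn-in is monotone and AI converges", {
  sim <- smallSim(n = 150, m = 800, nQtl = 60, seed = 83)
  fit <- fitMvLMM(sim$grm, sim$pheno, "trait", emIterations = 6)
  expect_true(converged(fit))
  # EM phase: per-iteration log-likelihood never decreases
  emTrace <- fit@loglikTrace[1:7]
  expect_true(all(diff(emTrace) > -1e-8))
  # final log-likelihood is the running maximum
  expect_equal(logLikREML(fit), max(fit@loglikTrace), tolerance = 1e-8)
  # covariance matrices are symmetric PD and correlations are in range
  vc <- varComponents(fit)
  expect_true(all(eigen(vc$SigmaU, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(all(abs(geneticCorrelation(fit)) <= 1 + 1e-8))
})

test_that("three identical trait columns give genetic correlations near 1", {
  sim <- smallSim(n = 150, m = 600, nQtl = 50, seed = 91)
  v <- sim$pheno@values
  v[, "trait_140"] <- v[, "trait_70"]
  v[, "trait_210"] <- v[, "trait_70"]
  p <- PhenotypeTable(sim$pheno@ids, sim$pheno@sex, sim$pheno@batch, v)
  fit <- fitMvLMM(sim$grm, p, "trait", tol = 1e-6)
  rg <- geneticCorrelation(fit)[upper.tri(diag(3))]
  expect_true(all(rg >= 0.99))
})

test_that("multivariate prediction identity holds with missing patterns", {
  sim <- smallSim(n = 150, m = 600, nQtl = 50, seed = 97)
  ids <- individualIds(sim$g)
  p <- maskRecords(sim$pheno, ids[1:25], "trait", 2:3)  # partial records
  fit <- fitMvLMM(sim$grm, p, "trait", tol = 1e-6)
  # agreement is up to the 1e-4 stabilizing diagonal shift the fit applies
  pred <- predictGEBV(fit, sim$grm, ids)
  expect_equal(unname(pred), unname(gebv(fit)), tolerance = 1e-3)
  # masked animals keep records at time 1 only
  expect_false(any(ids[1:25] %in% fit@recordIds[[2]]))
  expect_true(all(ids[1:25] %in% fit@recordIds[[1]]))
})
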