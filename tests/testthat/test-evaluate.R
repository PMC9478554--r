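test_that("corrected phenotypes are OLS residuals of sex and batch", {
  sim <- smallSim(n = 120, m = 300, nQtl = 30, seed = 15)
  p <- sim$pheno
  yc <- correctPhenotypes(p)
  # matches the normal-equations oracle
  X <- cbind(1, as.numeric(p@sex == "M"),
             model.matrix(~ batch - 1, data.frame(batch = p@batch))[, -1])
  for (j in colnames(p@values))
    expect_equal(unname(yc[, j]), olsResidOracle(p@values[, j], X),
                 tolerance = 1e-10)
  # mean-zero because the intercept is part of the removal
  expect_lt(max(abs(colMeans(yc))), 1e-10)
  # orthogonal to the sex indicator
  expect_lt(abs(cor(yc[, "trait_140"], as.numeric(p@sex == "M"))), 1e-10)

  # records fully determined by batch are corrected to exactly zero
  ids <- paste0("i", 1:40)
  batch <- factor(rep(c("b1", "b2"), each = 20))
  v <- matrix(rep(ifelse(batch == "b1", 1, 3), 3), ncol = 3,
              dimnames = list(ids, c("t_70", "t_140", "t_210")))
  p0 <- PhenotypeTable(ids, factor(rep(c("F", "M"), 20)), batch, v)
  expect_lt(max(abs(correctPhenotypes(p0))), 1e-12)
})

test_that("fold assignment is balanced, seeded and exhaustive", {
  ids <- sprintf("r%03d", 1:629)
  fa <- makeFolds(ids, 10, seed = 4)
  sizes <- sort(tabulate(fa@fold, 10))
  expect_equal(sizes, c(62, rep(63, 9)))
  expect_setequal(names(fa@fold), ids)
  expect_identical(fa@fold, makeFolds(ids, 10, seed = 4)@fold)
  expect_false(identical(fa@fold, makeFolds(ids, 10, seed = 5)@fold))
  # one individual per fold when n = nFolds
  expect_equal(sort(tabulate(makeFolds(ids[1:10], 10, seed = 1)@fold, 10)),
               rep(1L, 10))
  expect_error(makeFolds(ids, 1), "at least 2")
  expect_error(makeFolds(ids[1:5], 10), "more folds")
})

test_that("accuracy is a guarded Pearson correlation", {
  yc <- c(0.3, -0.2, 0.5, 1.1, -0.7)
  expect_equal(accuracy(yc, yc), 1.0)
  expect_equal(accuracy(yc, -2 * yc + 5), -1.0)
  expect_true(is.na(accuracy(yc[1:2], yc[1:2])))        # too few pairs
  expect_true(is.na(accuracy(yc, rep(1, 5))))           # zero variance
  # null sampling distribution at validation-fold size
  set.seed(9)
  r <- replicate(400, accuracy(rnorm(63), rnorm(63)))
  expect_lt(mean(abs(r) >= 0.35), 0.05)
})

test_that("Welch comparison matches the textbook formula and conventions", {
  expect_equal(compareAccuracies(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 4), tolerance = 1e-12)
  cst <- rep(0.5, 5)
  expect_equal(compareAccuracies(cst, cst)$p, 1)
  expect_equal(compareAccuracies(cst, cst + 1)$p, 0)
  set.seed(3)
  b <- rnorm(30, 0.2, 0.05)
  a <- b + 10 * sd(b)
  expect_lt(compareAccuracies(a, b)$p, 1e-6)
  for (k in 1:10) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    got <- compareAccuracies(x, y)
    want <- welchOracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("cross-validation masks exactly the strategy's records", {
  sim <- smallSim(n = 160, m = 600, nQtl = 60, seed = 27)
  folds <- makeFolds(individualIds(sim$g), 4, seed = 2)
  valIds <- names(folds@fold)[folds@fold == 1]

  # mvLMM strategy: validation animals have no records at all in the fit
  masked <- maskRecords(sim$pheno, valIds, "trait", 1:3)
  fit <- fitMvLMM(sim$grm, masked, "trait", tol = 1e-6)
  for (t in 1:3) expect_false(any(valIds %in% fit@recordIds[[t]]))

  # mvLMM3 keeps the first two time points of validation animals
  masked3 <- maskRecords(sim$pheno, valIds, "trait", 3)
  fit3 <- fitMvLMM(sim$grm, masked3, "trait", tol = 1e-6)
  expect_true(all(valIds %in% fit3@recordIds[[1]]))
  expect_true(all(valIds %in% fit3@recordIds[[2]]))
  expect_false(any(valIds %in% fit3@recordIds[[3]]))

  # runCV reports the flags and bounded accuracies
  cv <- runCV(sim$grm, sim$pheno, "trait", "mvLMM23", folds, tol = 1e-6)
  tab <- cv@table
  expect_equal(nrow(tab), 4 * 3)
  expect_true(all(tab$observedInValidation == rep(c(TRUE, FALSE, FALSE), 4)))
  ok <- !is.na(tab$accuracy)
  expect_true(all(abs(tab$accuracy[ok]) <= 1))
  m <- meanAccuracy(cv)
  expect_equal(length(m), 3)
  mp <- meanAccuracy(cv, pooled = TRUE)
  expect_equal(length(mp), 3)
})

test_that("uvLMM cross-validation accuracy sits in the plausible band", {
  sim <- smallSim(n = 300, m = 2000, nQtl = 100, seed = 37)
  folds <- makeFolds(individualIds(sim$g), 5, seed = 3)
  cv <- runCV(sim$grm, sim$pheno, "trait", "uvLMM", folds)
  acc <- meanAccuracy(cv)[["140"]]
  expect_gt(acc, 0)
  expect_lt(acc, sqrt(0.3) + 0.1)
})

test_that("a single-density scan with one replicate equals the direct fit", {
  sim <- smallSim(n = 100, m = 400, nQtl = 40, seed = 45)
  scan <- densityScan(sim$g, sim$pheno, "trait", densities = 400,
                      nReps = 1, baseSeed = 5, doCV = FALSE)
  direct <- vapply(c(70, 140, 210), function(t)
    heritability(fitUvLMM(sim$grm, sim$pheno, "trait", t)), numeric(1))
  expect_equal(scan@estimates$h2, direct, tolerance = 1e-8)
  expect_equal(nrow(scan@grmCorrelations), 0L)
})

test_that("a 30-replicate density has choose(30, 2) GRM correlation pairs", {
  sim <- smallSim(n = 40, m = 120, nQtl = 10, seed = 51)
  scan <- densityScan(sim$g, sim$pheno, "trait", densities = 60,
                      nReps = 30, baseSeed = 7, doCV = FALSE)
  expect_equal(nrow(scan@grmCorrelations), choose(30, 2))
  expect_equal(nrow(scan@estimates), 30 * 3)
  # replicate seeds are recorded and deterministic
  scan2 <- densityScan(sim$g, sim$pheno, "trait", densities = 60,
                       nReps = 30, baseSeed = 7, doCV = FALSE)
  expect_identical(scan@estimates$h2, scan2@estimates$h2)
})

test_that("the run configuration schema rejects unknown keys", {
  good <- list(seed = 3, experiment = list(densities = c(500, 1000),
                                           nReps = 2, doCV = FALSE))
  expect_silent(validateRunConfig(good))
  expect_error(validateRunConfig(c(good, list(bogus = 1))), "bogus")
  expect_error(validateRunConfig(list(experiment = list(densities = "a"))),
               "invalid value")
  expect_error(validateRunConfig(list(qc = list(mafMax = 0.1))),
               "unknown config key: /qc/mafMax")
})

test_that("fit serialization writes the documented JSON layout", {
  sim <- smallSim(n = 80, m = 200, nQtl = 20, seed = 57)
  fit <- fitUvLMM(sim$grm, sim$pheno, "trait", 140)
  f <- tempfile(fileext = ".json")
  writeFit(fit, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$model, "uv")
  expect_equal(js$varComponents$sigma2u, fit@sigma2u, tolerance = 1e-12)
  expect_equal(js$heritability$h2, fit@h2, tolerance = 1e-12)
  g <- tempfile(fileext = ".csv")
  writeGEBV(fit, g)
  got <- read.csv(g)
  expect_equal(got$gebv, unname(gebv(fit)), tolerance = 1e-6)
})
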