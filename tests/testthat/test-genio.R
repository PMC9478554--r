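test_that("matrix-csv genotypes round-trip and allele frequencies are in-sample", {
  d <- matrix(c(0, 2, 2, 0), 2, 2,
              dimnames = list(c("i1", "i2"), c("m1", "m2")))
  g <- GenotypeMatrix(d)
  expect_equal(unname(alleleFreq(g)), c(0.5, 0.5))

  f <- tempfile(fileext = ".csv")
  writeGenotypes(g, f, "matrix-csv")
  g2 <- readGenotypes(f, "matrix-csv")
  expect_identical(dosages(g2), dosages(g))

  # empty marker set is rejected
  expect_error(GenotypeMatrix(d[, 0, drop = FALSE]), "at least one marker")
  # duplicated ids are rejected
  dd <- d; rownames(dd) <- c("i1", "i1")
  expect_error(GenotypeMatrix(dd), "duplicated")
})

test_that("PLINK bed round-trip preserves dosages, coordinates and missing", {
  sim <- smallSim(n = 37, m = 53, nQtl = 10, seed = 3,
                  genoMissingRate = 0.05)
  prefix <- tempfile()
  writeGenotypes(sim$g, prefix, "plink-bed")
  g2 <- readGenotypes(paste0(prefix, ".bed"))
  expect_identical(dosages(g2), dosages(sim$g))
  expect_identical(chromosomes(g2), chromosomes(sim$g))
  expect_identical(positions(g2), positions(sim$g))
})

test_that("VCF genotypes are read from GT calls and DS dosages", {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"))
  rowsGT <- c(
    paste("1", "100", "v1", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T", ".", ".", ".", "GT",
          "1|1", "./.", "0/1", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, rowsGT), f)
  g <- readGenotypes(f, "vcf")
  expect_equal(unname(dosages(g)[, "v1"]), c(0, 1, 2))
  expect_equal(unname(dosages(g)[, "v2"]), c(2, NA, 1))
  expect_equal(positions(g), c(100L, 200L))

  rowsDS <- c(
    paste("1", "100", "v1", "A", "G", ".", ".", ".", "GT:DS",
          "0/0:0.12", "0/1:0.97", "1/1:1.88", sep = "\t"))
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, rowsDS), f2)
  g2 <- readGenotypes(f2, "vcf")
  expect_equal(unname(dosages(g2)[, "v1"]), c(0.12, 0.97, 1.88))
})

test_that("phenotype CSV round-trips with missing records", {
  sim <- smallSim(n = 40, m = 60, nQtl = 10, seed = 5)
  p <- maskRecords(sim$pheno, individualIds(sim$g)[1:4], "trait", 2)
  f <- tempfile(fileext = ".csv")
  writePhenotypes(p, f)
  p2 <- readPhenotypes(f)
  expect_equal(p2@values, p@values)
  expect_equal(as.character(p2@sex), as.character(p@sex))
  expect_equal(timePoints(p2), c(70, 140, 210))
})

test_that("qcFilter applies the MAF, missing-rate and HWE rules strictly", {
  # marker columns engineered by hand over 10 individuals
  ids <- paste0("i", 1:10)
  good <- c(0, 0, 1, 2, 1, 0, 1, 2, 0, 1)         # maf .4, passes
  mono <- rep(0, 10)                               # monomorphic, maf fail
  missy <- c(NA, NA, 1, 1, 0, 0, 1, 2, 0, 1)       # 2/10 missing, fail
  d <- cbind(good = good, mono = mono, missy = missy)
  rownames(d) <- ids
  res <- qcFilter(GenotypeMatrix(d))
  expect_equal(markerIds(res$genotypes), "good")
  expect_equal(res$report$reason, c(NA, "maf", "missing_rate"))

  # 12 AA / 12 aa with no heterozygote: far from HWE, p < 1e-6
  d24 <- cbind(good = rep(c(0, 1, 2), 8), hwe = rep(c(2, 0), each = 12))
  rownames(d24) <- paste0("j", 1:24)
  res24 <- qcFilter(GenotypeMatrix(d24))
  expect_equal(markerIds(res24$genotypes), "good")
  expect_equal(res24$report$reason, c(NA, "hwe"))
  expect_true(res24$report$hweP[2] < 1e-6)

  # the 4-individual hand count: dosages (0,0,1,2) -> freq 3/8 passes MAF
  g4 <- GenotypeMatrix(matrix(c(0, 0, 1, 2), 4, 1,
                              dimnames = list(paste0("x", 1:4), "mk")))
  r4 <- qcFilter(g4)
  expect_equal(r4$report$maf, 3 / 8)
  expect_true(r4$report$pass)

  # boundary strictness: maf exactly at the threshold fails (> is strict)
  gb <- GenotypeMatrix(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 1), 10, 1,
                              dimnames = list(ids, "mk")))  # maf = 0.1
  rb <- suppressWarnings(qcFilter(gb, qcThresholds(mafMin = 0.1)))
  expect_false(rb$report$pass)

  # removing everything warns and returns an empty result
  expect_warning(r0 <- qcFilter(GenotypeMatrix(matrix(0, 10, 2,
    dimnames = list(ids, c("a", "b"))))), "all markers removed")
  expect_null(r0$genotypes)
})

test_that("qcFilter is idempotent", {
  sim <- smallSim(n = 120, m = 400, nQtl = 20, seed = 9, mafLow = 0.02,
                  genoMissingRate = 0.06)
  r1 <- qcFilter(sim$g)
  expect_true(any(!r1$report$pass))      # the low-MAF panel loses markers
  r2 <- qcFilter(r1$genotypes)
  expect_true(all(r2$report$pass))
  expect_identical(markerIds(r2$genotypes), markerIds(r1$genotypes))
})

test_that("HWE exact test matches full enumeration", {
  expect_equal(hweExactTest(1, 0, 0), 1.0)
  expect_equal(hweExactTest(0, 2, 0), hweOracle(0, 2, 0))
  expect_equal(hweExactTest(500, 300, 200), hweOracle(500, 300, 200),
               tolerance = 1e-10)
  set.seed(42)
  for (k in 1:20) {
    cnt <- as.vector(rmultinom(1, sample(10:400, 1),
                               prob = c(0.3, 0.5, 0.2)))
    expect_equal(hweExactTest(cnt[1], cnt[2], cnt[3]),
                 hweOracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_error(hweExactTest(0, 0, 0), "zero")
})

test_that("HWE exact test is uniform-conservative under the null", {
  set.seed(101)
  n <- 200; p <- 0.3; reps <- 2000
  counts <- rmultinom(reps, n, prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  pv <- hweExactTest(counts[1, ], counts[2, ], counts[3, ])
  frac <- mean(pv <= 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("marker subsampling is uniform, seeded and order-preserving", {
  sim <- smallSim(n = 50, m = 10000, nQtl = 10, seed = 21)
  s1 <- subsampleMarkers(sim$g, 500, seed = 7)
  s2 <- subsampleMarkers(sim$g, 500, seed = 7)
  s3 <- subsampleMarkers(sim$g, 500, seed = 8)
  expect_equal(nMarkers(s1), 500)
  expect_identical(markerIds(s1), markerIds(s2))
  expect_false(identical(markerIds(s1), markerIds(s3)))
  expect_true(all(markerIds(s1) %in% markerIds(sim$g)))
  # order preserved as in the source
  expect_identical(markerIds(s1),
                   intersect(markerIds(sim$g), markerIds(s1)))
  # identity case
  expect_identical(markerIds(subsampleMarkers(sim$g, 10000, seed = 1)),
                   markerIds(sim$g))
  expect_error(subsampleMarkers(sim$g, 10001), "exceeds")

  # coupon-collector check: the union over seeds at k = n/2 covers everything
  gsmall <- sim$g[, 1:40]
  seen <- character()
  for (s in 1:60) seen <- union(seen, markerIds(subsampleMarkers(gsmall, 20,
                                                                 seed = s)))
  expect_setequal(seen, markerIds(gsmall))
})

test_that("mean imputation fills missing dosages with 2p and nothing else", {
  sim <- smallSim(n = 60, m = 100, nQtl = 10, seed = 13,
                  genoMissingRate = 0.1)
  gi <- imputeMissing(sim$g)
  expect_false(anyNA(dosages(gi)))
  na <- is.na(dosages(sim$g))
  expect_identical(dosages(gi)[!na], dosages(sim$g)[!na])
  p2 <- 2 * alleleFreq(sim$g)
  idx <- which(na, arr.ind = TRUE)
  expect_equal(dosages(gi)[na], unname(p2[idx[, 2]]))
})
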