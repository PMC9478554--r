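#' Synthetic population configuration
#'
#' Parameters of the synthetic data generator. The defaults emulate the
#' structure of the study population the package is designed around: 629
#' individuals (298 males, 331 females), one trait measured at 70, 140 and
#' 210 days of age, low-to-moderate heritabilities, and strong positive
#' genetic correlations between ages.
#'
#' @slot nIndividuals population size.
#' @slot nMarkers number of biallelic SNPs.
#' @slot nChromosomes markers are split evenly over this many chromosomes.
#' @slot ldRho adjacent-marker haplotype copy probability in \[0, 1);
#'   0 gives independent markers. The default 0.97 is calibrated so the
#'   panel carries a few hundred effective segments, matching the
#'   heritability standard errors (about 0.04-0.06) that genome-wide
#'   analyses at this sample size report; see the methods vignette.
#' @slot mafLow,mafHigh bounds of the uniform per-marker MAF distribution.
#' @slot nQtl number of causal markers (shared across time points).
#' @slot h2 length-3 target heritabilities, each in (0, 1).
#' @slot geneticCorr 3x3 positive-definite genetic correlation matrix with
#'   unit diagonal.
#' @slot residCorr 3x3 residual correlation matrix (identity by default:
#'   residuals independent across time points).
#' @slot mean population mean added to every record.
#' @slot sexEffect additive shift for males (females are the reference).
#' @slot batchEffects per-batch additive shifts; their length sets the
#'   number of batches (assigned round-robin).
#' @slot maleFraction fraction of males (default 298/629).
#' @slot genoMissingRate fraction of dosages set missing after simulation.
#' @slot traitName name used for the phenotype columns.
#' @slot times measurement ages.
#' @slot seed RNG seed governing the whole simulation.
#' @export
setClass("SimConfig",
  representation(nIndividuals = "integer", nMarkers = "integer",
                 nChromosomes = "integer", ldRho = "numeric",
                 mafLow = "numeric", mafHigh = "numeric", nQtl = "integer",
                 h2 = "numeric", geneticCorr = "matrix", residCorr = "matrix",
                 mean = "numeric", sexEffect = "numeric",
                 batchEffects = "numeric", maleFraction = "numeric",
                 genoMissingRate = "numeric", traitName = "character",
                 times = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 2) msg <- c(msg, "need at least 2 individuals")
  if (object@nMarkers < 1) msg <- c(msg, "need at least 1 marker")
  if (object@ldRho < 0 || object@ldRho >= 1) msg <- c(msg, "ldRho must be in [0, 1)")
  if (object@mafLow <= 0 || object@mafHigh > 0.5 || object@mafLow > object@mafHigh)
    msg <- c(msg, "need 0 < mafLow <= mafHigh <= 0.5")
  if (object@nQtl < 1 || object@nQtl > object@nMarkers)
    msg <- c(msg, "nQtl must be in [1, nMarkers]")
  k <- length(object@times)
  if (length(object@h2) != k) msg <- c(msg, "h2 must have one entry per time point")
  if (any(object@h2 <= 0 | object@h2 >= 1)) msg <- c(msg, "h2 entries must be in (0, 1)")
  gc <- object@geneticCorr
  if (!all(dim(gc) == k)) msg <- c(msg, "geneticCorr must be times x times")
  else {
    if (max(abs(gc - t(gc))) > 1e-12 || any(abs(diag(gc) - 1) > 1e-12))
      msg <- c(msg, "geneticCorr must be symmetric with unit diagonal")
    else if (min(eigen(gc, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      msg <- c(msg, "geneticCorr must be positive definite")
  }
  if (!all(dim(object@residCorr) == k)) msg <- c(msg, "residCorr must be times x times")
  if (object@maleFraction <= 0 || object@maleFraction >= 1)
    msg <- c(msg, "maleFraction must be in (0, 1)")
  if (object@genoMissingRate < 0 || object@genoMissingRate >= 1)
    msg <- c(msg, "genoMissingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nIndividuals,nMarkers,nChromosomes,ldRho,mafLow,mafHigh,nQtl see
#'   the slot documentation.
#' @param h2,geneticCorr,residCorr,mean,sexEffect,batchEffects see the slot
#'   documentation. `geneticCorr` may be given as a single off-diagonal
#'   value.
#' @param maleFraction,genoMissingRate,traitName,times,seed see the slot
#'   documentation.
#' @export
simParams <- function(nIndividuals = 629, nMarkers = 10000,
                      nChromosomes = 21, ldRho = 0.97,
                      mafLow = 0.05, mafHigh = 0.5, nQtl = 200,
                      h2 = c(0.05, 0.30, 0.30), geneticCorr = 0.8,
                      residCorr = NULL, mean = 10, sexEffect = 0.5,
                      batchEffects = c(0, 0.5, 1), maleFraction = 298 / 629,
                      genoMissingRate = 0, traitName = "trait",
                      times = c(70, 140, 210), seed = 1L) {
  k <- length(times)
  if (is.matrix(geneticCorr)) {
    gc <- geneticCorr
  } else {
    gc <- matrix(geneticCorr, k, k)
    diag(gc) <- 1
  }
  if (is.null(residCorr)) residCorr <- diag(k)
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nMarkers = as.integer(nMarkers), nChromosomes = as.integer(nChromosomes),
      ldRho = ldRho, mafLow = mafLow, mafHigh = mafHigh,
      nQtl = as.integer(nQtl), h2 = h2, geneticCorr = gc,
      residCorr = residCorr, mean = mean, sexEffect = sexEffect,
      batchEffects = batchEffects, maleFraction = maleFraction,
      genoMissingRate = genoMissingRate, traitName = traitName,
      times = as.numeric(times), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nIndividuals, "individuals,", object@nMarkers,
      "markers on", object@nChromosomes, "chromosomes\n")
  cat("  ldRho =", object@ldRho, ", MAF in [", object@mafLow, ",",
      object@mafHigh, "],", object@nQtl, "QTL\n")
  cat("  h2 =", paste(object@h2, collapse = "/"),
      ", genetic corr =", object@geneticCorr[1, 2], ", seed =", object@seed, "\n")
})

#' Ground truth of a simulated population
#'
#' @slot tbv true breeding values, individuals x time points.
#' @slot qtlIds marker ids of the causal loci.
#' @slot qtlEffects causal effect sizes, QTL x time points (on the rescaled
#'   scale actually used to build the breeding values).
#' @slot realizedH2 realized variance ratios `var(u)/(var(u)+var(e))` per
#'   time point (exact by construction, since the generator rescales the
#'   realized samples).
#' @export
setClass("TrueValues",
  representation(tbv = "matrix", qtlIds = "character",
                 qtlEffects = "matrix", realizedH2 = "numeric"))

setMethod("show", "TrueValues", function(object) {
  cat("TrueValues:", nrow(object@tbv), "individuals,",
      length(object@qtlIds), "QTL\n")
  cat("  realized h2:", paste(sprintf("%.4f", object@realizedH2),
                              collapse = ", "), "\n")
})

#' Simulate LD-structured genotypes
#'
#' Haplotypes are first-order Markov chains along each chromosome: marker
#' `k` copies marker `k-1`'s allele with probability `ldRho` and otherwise
#' draws fresh from `Bernoulli(p_k)` with `p_k ~ U(mafLow, mafHigh)`. Two
#' haplotypes are summed per individual. Deterministic under the config
#' seed.
#'
#' @param cfg a [SimConfig-class]
#' @return a [GenotypeMatrix-class] with integer dosages (and missing
#'   entries when `genoMissingRate > 0`).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  withSeed(cfg@seed, {
    n <- cfg@nIndividuals
    m <- cfg@nMarkers
    nh <- 2L * n
    perChr <- diff(round(seq(0, m, length.out = cfg@nChromosomes + 1)))
    perChr <- perChr[perChr > 0]
    p <- runif(m, cfg@mafLow, cfg@mafHigh)
    D <- matrix(0, n, m)
    off <- 0L
    for (mc in perChr) {
      H <- matrix(0L, nh, mc)
      H[, 1] <- rbinom(nh, 1L, p[off + 1L])
      if (mc > 1) for (k in 2:mc) {
        h <- rbinom(nh, 1L, p[off + k])
        cp <- runif(nh) < cfg@ldRho
        h[cp] <- H[cp, k - 1L]
        H[, k] <- h
      }
      D[, (off + 1L):(off + mc)] <- H[1:n, , drop = FALSE] +
        H[(n + 1L):nh, , drop = FALSE]
      off <- off + mc
    }
    rownames(D) <- sprintf("ind%04d", seq_len(n))
    colnames(D) <- sprintf("snp%07d", seq_len(m))
    if (cfg@genoMissingRate > 0) {
      nm <- rbinom(1, n * m, cfg@genoMissingRate)
      D[sample.int(n * m, nm)] <- NA_real_
    }
    chrom <- rep(seq_along(perChr), times = perChr)
    spacing <- 100000L
    pos <- unlist(lapply(perChr, function(k) seq_len(k) * spacing),
                  use.names = FALSE)
    GenotypeMatrix(D, chrom = as.character(chrom), pos = pos)
  })
}

#' Simulate phenotypes with known breeding values
#'
#' For individual `i` at time point `t`:
#' `y_it = mean + sex_i + batch_i + u_it + e_it`, where the breeding values
#' `u` are built from `nQtl` shared causal markers with effect vectors drawn
#' from a multivariate normal with correlation `geneticCorr` (pleiotropy),
#' and `e` is multivariate normal with correlation `residCorr`. Both are
#' rescaled on the realized samples so that
#' `var(u_t) / (var(u_t) + var(e_t))` hits the target `h2[t]` exactly, with
#' unit phenotypic scale.
#'
#' @param g a [GenotypeMatrix-class], typically from [simulateGenotypes()]
#' @param cfg the [SimConfig-class] used (QTL count, h2, correlations, fixed
#'   effects). Phenotype randomness is seeded from `cfg@seed` offset by one,
#'   so it is reproducible yet distinct from the genotype stream.
#' @return a list with `phenotypes` (a [PhenotypeTable-class]) and
#'   `trueValues` (a [TrueValues-class]).
#' @export
simulatePhenotypes <- function(g, cfg) {
  stopifnot(is(g, "GenotypeMatrix"), is(cfg, "SimConfig"))
  if (cfg@nQtl > nMarkers(g)) stop("nQtl exceeds the number of markers")
  k <- length(cfg@times)
  cholG <- tryCatch(chol(cfg@geneticCorr),
                    error = function(e) stop("geneticCorr is not positive definite"))
  cholE <- tryCatch(chol(cfg@residCorr),
                    error = function(e) stop("residCorr is not positive definite"))
  withSeed(cfg@seed + 1L, {
    n <- nIndividuals(g)
    p <- alleleFreq(g)
    poly <- which(p > 0 & p < 1)
    if (length(poly) < cfg@nQtl) stop("not enough polymorphic markers for the QTL")
    qtl <- sort(sample(poly, cfg@nQtl))
    Wq <- sweep(dosages(imputeMissing(g))[, qtl, drop = FALSE], 2, 2 * p[qtl])
    beta <- matrix(rnorm(cfg@nQtl * k), cfg@nQtl, k) %*% cholG
    u <- Wq %*% beta
    e <- matrix(rnorm(n * k), n, k) %*% cholE
    sdu <- apply(u, 2, sd)
    if (any(sdu == 0)) stop("degenerate breeding values (zero variance)")
    su <- sqrt(cfg@h2) / sdu
    se <- sqrt(1 - cfg@h2) / apply(e, 2, sd)
    u <- sweep(u, 2, su, "*")
    beta <- sweep(beta, 2, su, "*")
    e <- sweep(e, 2, se, "*")
    nMale <- round(cfg@maleFraction * n)
    sex <- factor(sample(rep(c("M", "F"), c(nMale, n - nMale))),
                  levels = c("F", "M"))
    nB <- length(cfg@batchEffects)
    batch <- factor(rep(paste0("b", seq_len(nB)), length.out = n),
                    levels = paste0("b", seq_len(nB)))
    fixed <- cfg@mean + cfg@sexEffect * (sex == "M") +
      cfg@batchEffects[as.integer(batch)]
    Y <- sweep(u + e, 1, fixed, "+")
    colnames(Y) <- paste(cfg@traitName, cfg@times, sep = "_")
    ids <- individualIds(g)
    rownames(Y) <- ids
    realized <- apply(u, 2, var) / (apply(u, 2, var) + apply(e, 2, var))
    tbv <- u
    rownames(tbv) <- ids
    colnames(tbv) <- as.character(cfg@times)
    list(phenotypes = PhenotypeTable(ids, sex, batch, Y, times = cfg@times),
         trueValues = new("TrueValues", tbv = tbv,
                          qtlIds = markerIds(g)[qtl], qtlEffects = beta,
                          realizedH2 = as.numeric(realized)))
  })
}

#' Mask phenotype records
#'
#' Sets the records of the given individuals at the given time points of one
#' trait to missing; all other cells are untouched. This is the injector the
#' cross-validation leave-out strategies are built on.
#'
#' @param p a [PhenotypeTable-class]
#' @param ids individuals whose records are masked.
#' @param trait trait name.
#' @param timeIdx indices into `timePoints(p)` of the time points to mask
#'   (default: all).
#' @return a [PhenotypeTable-class]
#' @export
maskRecords <- function(p, ids, trait, timeIdx = seq_along(p@times)) {
  stopifnot(is(p, "PhenotypeTable"))
  bad <- setdiff(ids, p@ids)
  if (length(bad)) stop("unknown ids: ", paste(head(bad, 3), collapse = ", "))
  cols <- paste(trait, p@times[timeIdx], sep = "_")
  v <- p@values
  v[match(ids, p@ids), cols] <- NA_real_
  PhenotypeTable(p@ids, p@sex, p@batch, v, times = p@times)
}

#' Write true breeding values to CSV
#'
#' @param tv a [TrueValues-class]
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrueValues <- function(tv, path) {
  df <- data.frame(id = rownames(tv@tbv), tv@tbv, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
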