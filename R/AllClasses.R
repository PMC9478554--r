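#' Genotype dosage matrix
#'
#' Holds biallelic SNP genotypes as allele dosages in \[0, 2\] for a set of
#' individuals, together with marker coordinates. Missing genotypes are `NA`
#' (never 0). Allele frequencies are always computed in-sample from the
#' current matrix via [alleleFreq()], so they stay consistent after any
#' filtering or subsampling.
#'
#' @slot dosages numeric matrix, individuals in rows (rownames are the
#'   individual ids), markers in columns (colnames are the marker ids);
#'   entries in \[0, 2\] or `NA`.
#' @slot chrom character vector, per-marker chromosome.
#' @slot pos integer vector, per-marker 1-based position.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", chrom = "character", pos = "integer"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "dosages must be numeric")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosages must have individual ids as rownames and marker ids as colnames")
  if (ncol(d) < 1L) msg <- c(msg, "at least one marker is required")
  if (nrow(d) < 1L) msg <- c(msg, "at least one individual is required")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicated individual ids")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicated marker ids")
  if (length(object@chrom) != ncol(d)) msg <- c(msg, "chrom length != number of markers")
  if (length(object@pos) != ncol(d)) msg <- c(msg, "pos length != number of markers")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of allele dosages (individuals x markers)
#'   with individual ids as rownames and marker ids as colnames. Missing
#'   genotypes must be `NA`.
#' @param chrom per-marker chromosome labels; recycled default `"0"`.
#' @param pos per-marker 1-based positions; default `1:nMarkers`.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("m1", "m2")))
#' g <- GenotypeMatrix(d)
#' alleleFreq(g)
#' @export
GenotypeMatrix <- function(dosages, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(chrom)) chrom <- rep("0", ncol(dosages))
  if (is.null(pos)) pos <- seq_len(ncol(dosages))
  new("GenotypeMatrix", dosages = dosages,
      chrom = as.character(chrom), pos = as.integer(pos))
}

#' @describeIn GenotypeMatrix the dosage matrix
#' @param x a GenotypeMatrix
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix individual ids
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @describeIn GenotypeMatrix marker ids
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosages))

#' @describeIn GenotypeMatrix number of individuals
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@dosages))

#' @describeIn GenotypeMatrix number of markers
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @describeIn GenotypeMatrix per-marker chromosome labels
#' @export
setMethod("chromosomes", "GenotypeMatrix", function(x) x@chrom)

#' @describeIn GenotypeMatrix per-marker 1-based positions
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@pos)

#' @describeIn GenotypeMatrix in-sample alternate-allele frequency per marker:
#'   column sum over twice the number of non-missing genotypes.
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(x) {
  d <- x@dosages
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "markers\n")
  nm <- sum(is.na(object@dosages))
  cat("  missing dosages:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / length(object@dosages)))
  cat("  chromosomes:", length(unique(object@chrom)), "\n")
})

#' Phenotype table
#'
#' Per-individual sex, batch and trait values measured at a fixed set of time
#' points (default 70, 140 and 210 days of age). Missing records are `NA`.
#' Value columns are named `<trait>_<time>`.
#'
#' @slot ids character, individual ids.
#' @slot sex factor with two levels.
#' @slot batch factor with at least one level.
#' @slot values numeric matrix, individuals x (trait, time) columns.
#' @slot traits character, trait names.
#' @slot times numeric, time points (days of age).
#' @export
setClass("PhenotypeTable",
  representation(ids = "character", sex = "factor", batch = "factor",
                 values = "matrix", traits = "character", times = "numeric"))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicated individual ids")
  if (length(object@sex) != n) msg <- c(msg, "sex length != n")
  if (length(object@batch) != n) msg <- c(msg, "batch length != n")
  if (nrow(object@values) != n) msg <- c(msg, "values rows != n")
  if (!length(levels(object@sex))) msg <- c(msg, "sex has no levels")
  if (!length(levels(object@batch))) msg <- c(msg, "batch has no levels")
  v <- object@values
  if (any(!is.finite(v) & !is.na(v))) msg <- c(msg, "non-finite phenotype values")
  want <- as.vector(outer(object@traits, object@times, paste, sep = "_"))
  if (!all(want %in% colnames(v)))
    msg <- c(msg, "values must have a <trait>_<time> column per trait and time")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeTable
#'
#' @param ids individual ids.
#' @param sex two-level factor (or coercible).
#' @param batch factor (or coercible) with at least one level.
#' @param values numeric matrix with columns named `<trait>_<time>`.
#' @param times measurement time points; default `c(70, 140, 210)`.
#' @return a [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(ids, sex, batch, values, times = c(70, 140, 210)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  traits <- unique(sub("_[^_]+$", "", colnames(values)))
  new("PhenotypeTable", ids = as.character(ids), sex = as.factor(sex),
      batch = as.factor(batch), values = values, traits = traits,
      times = as.numeric(times))
}

#' @describeIn PhenotypeTable individual ids
#' @param x a PhenotypeTable
#' @export
setMethod("individualIds", "PhenotypeTable", function(x) x@ids)

#' @describeIn PhenotypeTable number of individuals
#' @export
setMethod("nIndividuals", "PhenotypeTable", function(x) length(x@ids))

#' @describeIn PhenotypeTable trait names
#' @export
setMethod("traitNames", "PhenotypeTable", function(x) x@traits)

#' @describeIn PhenotypeTable measurement time points
#' @export
setMethod("timePoints", "PhenotypeTable", function(x) x@times)

#' @describeIn PhenotypeTable matrix of one trait's records, one column per
#'   time point
#' @param trait trait name
#' @export
setMethod("traitValues", "PhenotypeTable", function(x, trait) {
  if (!trait %in% x@traits) stop("unknown trait: ", trait)
  cols <- paste(trait, x@times, sep = "_")
  m <- x@values[, cols, drop = FALSE]
  colnames(m) <- as.character(x@times)
  m
})

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", length(object@ids), "individuals,",
      length(object@traits), "trait(s) at times",
      paste(object@times, collapse = "/"), "\n")
  cat("  sex:", paste(sprintf("%s=%d", levels(object@sex),
                              tabulate(object@sex)), collapse = ", "), "\n")
  cat("  batches:", nlevels(object@batch), "\n")
  cat("  missing records:", sum(is.na(object@values)), "\n")
})

#' Marker QC thresholds
#'
#' Thresholds for [qcFilter()]: markers are retained when MAF is strictly
#' above `mafMin`, the missing-genotype fraction strictly below
#' `missingRateMax`, and the Hardy-Weinberg exact-test p-value strictly above
#' `hwePMin`.
#'
#' @slot mafMin minimum minor allele frequency (exclusive), default 0.05.
#' @slot missingRateMax maximum missing rate (exclusive), default 0.10.
#' @slot hwePMin minimum HWE exact p-value (exclusive), default 1e-6.
#' @export
setClass("QCThresholds",
  representation(mafMin = "numeric", missingRateMax = "numeric",
                 hwePMin = "numeric"))

setValidity("QCThresholds", function(object) {
  v <- c(object@mafMin, object@missingRateMax, object@hwePMin)
  if (length(v) != 3 || any(!is.finite(v)) || any(v < 0) || any(v > 1))
    "all thresholds must be single values in [0, 1]" else TRUE
})

#' @rdname QCThresholds-class
#' @param mafMin,missingRateMax,hwePMin see slot documentation.
#' @export
qcThresholds <- function(mafMin = 0.05, missingRateMax = 0.10, hwePMin = 1e-6) {
  new("QCThresholds", mafMin = mafMin, missingRateMax = missingRateMax,
      hwePMin = hwePMin)
}

#' Genomic relationship matrix (VanRaden)
#'
#' Symmetric individuals x individuals relationship matrix
#' `G = W W' / (2 sum p_k (1 - p_k))` with `W` the column-centred dosage
#' matrix. With in-sample allele frequencies the columns of `W` are centred,
#' so every row of `G` sums to zero.
#'
#' @slot mat symmetric numeric matrix with individual ids as dimnames.
#' @slot nMarkersUsed number of markers that entered the matrix.
#' @slot denom the scaling denominator `2 sum p_k (1 - p_k)`.
#' @export
setClass("GRM",
  representation(mat = "matrix", nMarkersUsed = "integer", denom = "numeric"))

setValidity("GRM", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix not square")
  if (is.null(rownames(m))) msg <- c(msg, "matrix must carry individual ids as dimnames")
  if (max(abs(m - t(m))) > 1e-10 * max(1, max(abs(m))))
    msg <- c(msg, "matrix not symmetric")
  if (!is.na(object@denom) && object@denom <= 0)
    msg <- c(msg, "denominator must be positive")  # NA when read from disk
  if (length(msg)) msg else TRUE
})

#' @describeIn GRM the relationship matrix
#' @param x a GRM
#' @export
setMethod("grmMatrix", "GRM", function(x) x@mat)

#' @describeIn GRM individual ids
#' @export
setMethod("individualIds", "GRM", function(x) rownames(x@mat))

#' @describeIn GRM number of individuals
#' @export
setMethod("nIndividuals", "GRM", function(x) nrow(x@mat))

#' @describeIn GRM number of markers used to build the matrix
#' @export
setMethod("nMarkersUsed", "GRM", function(x) x@nMarkersUsed)

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@mat), "individuals, built from",
      object@nMarkersUsed, "markers\n")
  cat(sprintf("  mean diagonal: %.4f, denominator: %.2f\n",
              mean(diag(object@mat)), object@denom))
})

#' Univariate GBLUP REML fit
#'
#' Result of [fitUvLMM()]: REML estimates of the additive-genetic and
#' residual variances of `y = Xb + Zu + e` with `u ~ N(0, G sigma2u)`,
#' `e ~ N(0, I sigma2e)`, plus heritability with a delta-method standard
#' error and GEBVs for every individual in the GRM.
#'
#' @slot sigma2u additive-genetic variance estimate.
#' @slot sigma2e residual variance estimate.
#' @slot h2 heritability `sigma2u / (sigma2u + sigma2e)`.
#' @slot seH2 delta-method standard error of `h2` (NA at a boundary).
#' @slot beta named fixed-effect estimates.
#' @slot gebv named GEBVs for all individuals in the GRM.
#' @slot loglik REML log-likelihood at the optimum.
#' @slot nIterations optimizer iteration count (function evaluations).
#' @slot converged logical.
#' @slot boundary logical, TRUE when the genetic variance hit its floor.
#' @slot phenIds ids of the phenotyped (training) individuals.
#' @slot infoVec `V^{-1}(y - X beta)` on the phenotyped individuals;
#'   together with `sigma2u` it reproduces the BLUP for any target.
#' @export
setClass("UvFit",
  representation(sigma2u = "numeric", sigma2e = "numeric", h2 = "numeric",
                 seH2 = "numeric", beta = "numeric", gebv = "numeric",
                 loglik = "numeric", nIterations = "integer",
                 converged = "logical", boundary = "logical",
                 phenIds = "character", infoVec = "numeric"))

#' @describeIn UvFit heritability estimate
#' @param x a UvFit
#' @export
setMethod("heritability", "UvFit", function(x) x@h2)

#' @describeIn UvFit variance components `c(sigma2u, sigma2e)`
#' @export
setMethod("varComponents", "UvFit",
          function(x) c(sigma2u = x@sigma2u, sigma2e = x@sigma2e))

#' @describeIn UvFit named GEBV vector for all GRM individuals
#' @export
setMethod("gebv", "UvFit", function(x) x@gebv)

#' @describeIn UvFit convergence flag
#' @export
setMethod("converged", "UvFit", function(x) x@converged)

#' @describeIn UvFit REML log-likelihood
#' @export
setMethod("logLikREML", "UvFit", function(x) x@loglik)

setMethod("show", "UvFit", function(object) {
  cat("Univariate GBLUP REML fit\n")
  cat(sprintf("  sigma2u = %.4f, sigma2e = %.4f\n",
              object@sigma2u, object@sigma2e))
  cat(sprintf("  h2 = %.4f (SE %.4f), logLik = %.3f, converged: %s%s\n",
              object@h2, object@seH2, object@loglik, object@converged,
              if (object@boundary) " [boundary]" else ""))
  cat("  records:", length(object@phenIds), "of", length(object@gebv),
      "individuals\n")
})

#' Multivariate (three-time-point) GBLUP REML fit
#'
#' Result of [fitMvLMM()]: REML estimates of the 3x3 genetic and residual
#' covariance matrices of the multi-trait animal model with covariance
#' `SigmaU x G` (Kronecker), fitted by EM burn-in followed by
#' average-information REML on the mixed-model equations, supporting
#' arbitrary per-cell missing records.
#'
#' @slot SigmaU genetic covariance matrix (time points x time points).
#' @slot SigmaE residual covariance matrix.
#' @slot geneticCorr genetic correlation matrix derived from `SigmaU`.
#' @slot h2 per-time-point heritabilities.
#' @slot gebv matrix of GEBVs, individuals x time points.
#' @slot beta named fixed-effect estimates (stacked per time point).
#' @slot loglik REML log-likelihood at convergence.
#' @slot loglikTrace per-iteration REML log-likelihood.
#' @slot nIterations total iterations run.
#' @slot converged logical.
#' @slot PY weight matrix `R^{-1}(y - X beta - Z u)` (individuals x time
#'   points, zero at missing cells); reproduces BLUPs for any target.
#' @slot recordIds list: ids of the individuals with an observed record, per
#'   time point.
#' @slot times time-point labels.
#' @export
setClass("MvFit",
  representation(SigmaU = "matrix", SigmaE = "matrix", geneticCorr = "matrix",
                 h2 = "numeric", gebv = "matrix", beta = "numeric",
                 loglik = "numeric", loglikTrace = "numeric",
                 nIterations = "integer", converged = "logical",
                 PY = "matrix", recordIds = "list", times = "numeric"))

#' @describeIn MvFit per-time-point heritabilities
#' @param x an MvFit
#' @export
setMethod("heritability", "MvFit", function(x) x@h2)

#' @describeIn MvFit list with the genetic and residual covariance matrices
#' @export
setMethod("varComponents", "MvFit",
          function(x) list(SigmaU = x@SigmaU, SigmaE = x@SigmaE))

#' @describeIn MvFit genetic correlation matrix
#' @export
setMethod("geneticCorrelation", "MvFit", function(x) x@geneticCorr)

#' @describeIn MvFit GEBV matrix (individuals x time points)
#' @export
setMethod("gebv", "MvFit", function(x) x@gebv)

#' @describeIn MvFit convergence flag
#' @export
setMethod("converged", "MvFit", function(x) x@converged)

#' @describeIn MvFit REML log-likelihood
#' @export
setMethod("logLikREML", "MvFit", function(x) x@loglik)

setMethod("show", "MvFit", function(object) {
  cat("Multivariate GBLUP REML fit (", length(object@times),
      " time points)\n", sep = "")
  cat("  h2:", paste(sprintf("%.4f", object@h2), collapse = ", "), "\n")
  rg <- object@geneticCorr[upper.tri(object@geneticCorr)]
  cat("  genetic correlations:", paste(sprintf("%.3f", rg), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.3f after %d iterations, converged: %s\n",
              object@loglik, object@nIterations, object@converged))
})
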