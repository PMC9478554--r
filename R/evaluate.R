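#' @importFrom stats qr.resid t.test as.formula
#' @importFrom utils head
NULL

#' Fold assignment for k-fold cross-validation
#'
#' @slot fold integer fold index per individual, named by id.
#' @slot nFolds number of folds.
#' @slot seed the seed used for the shuffle.
#' @export
setClass("FoldAssignment",
  representation(fold = "integer", nFolds = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  sz <- tabulate(object@fold, object@nFolds)
  msg <- character()
  if (max(sz) - min(sz) > 1) msg <- c(msg, "fold sizes differ by more than 1")
  if (any(object@fold < 1 | object@fold > object@nFolds))
    msg <- c(msg, "fold index out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", length(object@fold), "individuals in",
      object@nFolds, "folds (sizes",
      paste(tabulate(object@fold, object@nFolds), collapse = "/"), ")\n")
})

#' Assign individuals to cross-validation folds
#'
#' Shuffles the ids under the seed and deals them round-robin, so fold sizes
#' differ by at most one (629 individuals in 10 folds gives nine folds of 63
#' and one of 62).
#'
#' @param ids individual ids.
#' @param nFolds number of folds (default 10, at least 2).
#' @param seed integer seed.
#' @return a [FoldAssignment-class]
#' @export
makeFolds <- function(ids, nFolds = 10, seed = 1) {
  n <- length(ids)
  if (nFolds < 2) stop("nFolds must be at least 2")
  if (nFolds > n) stop("more folds than individuals")
  shuffled <- withSeed(seed, sample(ids))
  fold <- integer(n)
  names(fold) <- ids
  fold[shuffled] <- rep(seq_len(nFolds), length.out = n)
  new("FoldAssignment", fold = fold, nFolds = as.integer(nFolds),
      seed = as.integer(seed))
}

#' Corrected phenotypes
#'
#' Removes the sex and batch effects (and the intercept) from every trait
#' column by ordinary least squares fitted on all phenotyped individuals, as
#' a general linear model. The result `yc = y - X beta_hat` is mean-zero per
#' column and is the evaluation target of the cross-validation accuracies.
#'
#' @param pheno a [PhenotypeTable-class]
#' @return a numeric matrix of the same shape as the phenotype values
#'   (missing records stay `NA`), with individual ids as rownames.
#' @export
correctPhenotypes <- function(pheno) {
  stopifnot(is(pheno, "PhenotypeTable"))
  X <- buildFixedDesign(pheno)
  v <- pheno@values
  yc <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    if (!length(obs)) next
    yc[obs, j] <- qr.resid(qr(X[obs, , drop = FALSE]), v[obs, j])
  }
  rownames(yc) <- pheno@ids
  yc
}

#' Prediction accuracy
#'
#' Pearson correlation between corrected phenotypes and GEBVs over their
#' complete pairs. Undefined correlations (fewer than 3 pairs or zero
#' variance) are reported as `NA`, never 0.
#'
#' @param yc corrected phenotypic values.
#' @param gebvHat predicted breeding values, aligned with `yc`.
#' @return Pearson correlation in \[-1, 1\], or `NA`.
#' @export
accuracy <- function(yc, gebvHat) {
  stopifnot(length(yc) == length(gebvHat))
  ok <- !is.na(yc) & !is.na(gebvHat)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(yc[ok]) == 0 || sd(gebvHat[ok]) == 0) return(NA_real_)
  cor(yc[ok], gebvHat[ok])
}

## Which time points a validation animal keeps in the training data, per
## leave-out strategy (times are ordered).
strategyMaskIdx <- function(model, nTimes) {
  switch(model,
         mvLMM = seq_len(nTimes),
         mvLMM23 = 2:nTimes,
         mvLMM3 = nTimes,
         stop("unknown model: ", model))
}

#' Cross-validation result
#'
#' @slot table per-fold accuracies: one row per fold x time point, with the
#'   validation size, whether that time point's records were observed in the
#'   validation animals during the fit, and the fold's convergence flag.
#' @slot model model tag.
#' @slot trait trait name.
#' @slot nFolds number of folds.
#' @export
setClass("CVResult",
  representation(table = "data.frame", model = "character",
                 trait = "character", nFolds = "integer"))

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", object@model, "on", object@trait, "with",
      object@nFolds, "folds\n")
  m <- meanAccuracy(object)
  for (i in seq_along(m))
    cat(sprintf("  time %s: mean accuracy %.4f\n", names(m)[i], m[i]))
})

#' @describeIn CVResult mean accuracy per time point over converged folds;
#'   `pooled = TRUE` instead correlates the pooled validation predictions
#'   across folds.
#' @param x a CVResult
#' @param pooled pool predictions across folds before correlating.
#' @export
setMethod("meanAccuracy", "CVResult", function(x, pooled = FALSE) {
  tab <- x@table[x@table$converged, , drop = FALSE]
  if (pooled) {
    out <- tapply(seq_len(nrow(tab)), tab$time, function(i) {
      accuracy(unlist(tab$yc[i]), unlist(tab$gebv[i]))
    })
  } else {
    out <- tapply(tab$accuracy, tab$time, mean, na.rm = TRUE)
  }
  out[as.character(sort(unique(x@table$time)))]
})

#' Run k-fold cross-validation of genomic prediction
#'
#' Implements the evaluation design: the GRM is built once on the full
#' population (prediction flows to validation animals through their genomic
#' relationships), corrected phenotypes are computed once on all records,
#' and per fold the validation animals' records are masked according to the
#' model's leave-out strategy before refitting:
#' \describe{
#'   \item{uvLMM}{each time point analysed separately; the validation
#'     animals' records at that time point are left out.}
#'   \item{mvLMM}{multivariate fit; all three time points left out.}
#'   \item{mvLMM23}{multivariate; the last two time points left out (the
#'     earliest record of each validation animal stays in).}
#'   \item{mvLMM3}{multivariate; only the last time point left out.}
#' }
#' Accuracy is the per-fold correlation between corrected phenotypes and
#' GEBVs in the validation set, reported for every time point (flagged when
#' that time point was observed in validation). Folds whose fit does not
#' converge are flagged and excluded from means. No masked record ever
#' enters a training fit; this is asserted against the fit's record list.
#'
#' @param geno a [GenotypeMatrix-class] or a prebuilt [GRM-class].
#' @param pheno a [PhenotypeTable-class]
#' @param trait trait name.
#' @param model one of `"uvLMM"`, `"mvLMM"`, `"mvLMM23"`, `"mvLMM3"`.
#' @param folds a [FoldAssignment-class] over the genotyped ids.
#' @param ... passed on to [fitUvLMM()] / [fitMvLMM()].
#' @return a [CVResult-class]
#' @export
runCV <- function(geno, pheno, trait, model = c("uvLMM", "mvLMM", "mvLMM23",
                                                "mvLMM3"),
                  folds, ...) {
  model <- match.arg(model)
  grm <- if (is(geno, "GRM")) geno else vanRadenGRM(geno)
  stopifnot(is(folds, "FoldAssignment"))
  ids <- individualIds(grm)
  if (!setequal(names(folds@fold), ids))
    stop("fold assignment does not cover the genotyped individuals")
  yc <- correctPhenotypes(pheno)
  times <- pheno@times
  nT <- length(times)
  rows <- list()
  for (f in seq_len(folds@nFolds)) {
    valIds <- intersect(names(folds@fold)[folds@fold == f], pheno@ids)
    if (model == "uvLMM") {
      for (ti in seq_len(nT)) {
        masked <- maskRecords(pheno, valIds, trait, timeIdx = ti)
        fit <- tryCatch(fitUvLMM(grm, masked, trait, times[ti], ...),
                        error = function(e) NULL)
        conv <- !is.null(fit) && converged(fit)
        acc <- NA_real_
        ycv <- gv <- rep(NA_real_, length(valIds))
        if (!is.null(fit)) {
          stopifnot(!any(valIds %in% fit@phenIds))   # leakage guard
          gv <- gebv(fit)[valIds]
          ycv <- yc[valIds, paste(trait, times[ti], sep = "_")]
          acc <- accuracy(ycv, gv)
        }
        rows[[length(rows) + 1]] <- data.frame(
          fold = f, time = times[ti], accuracy = acc,
          nValidation = length(valIds), observedInValidation = FALSE,
          converged = conv, yc = I(list(ycv)), gebv = I(list(gv)))
      }
    } else {
      maskIdx <- strategyMaskIdx(model, nT)
      masked <- maskRecords(pheno, valIds, trait, timeIdx = maskIdx)
      fit <- tryCatch(fitMvLMM(grm, masked, trait, ...),
                      error = function(e) NULL)
      conv <- !is.null(fit) && converged(fit)
      for (ti in seq_len(nT)) {
        acc <- NA_real_
        ycv <- gv <- rep(NA_real_, length(valIds))
        if (!is.null(fit)) {
          if (ti %in% maskIdx)                        # leakage guard
            stopifnot(!any(valIds %in% fit@recordIds[[ti]]))
          gv <- gebv(fit)[valIds, ti]
          ycv <- yc[valIds, paste(trait, times[ti], sep = "_")]
          acc <- accuracy(ycv, gv)
        }
        rows[[length(rows) + 1]] <- data.frame(
          fold = f, time = times[ti], accuracy = acc,
          nValidation = length(valIds),
          observedInValidation = !(ti %in% maskIdx), converged = conv,
          yc = I(list(ycv)), gebv = I(list(gv)))
      }
    }
  }
  tab <- do.call(rbind, rows)
  new("CVResult", table = tab, model = model, trait = trait,
      nFolds = folds@nFolds)
}

#' Marker-density scan result
#'
#' @slot estimates one row per density x replicate x time point:
#'   heritability, CV accuracy (when run), the replicate seed and fit flags.
#' @slot grmCorrelations all pairwise GRM correlations between replicates at
#'   each density.
#' @slot densities the scanned densities, ascending.
#' @slot nReps replicates per density.
#' @export
setClass("DensityScanResult",
  representation(estimates = "data.frame", grmCorrelations = "data.frame",
                 densities = "numeric", nReps = "integer"))

setMethod("show", "DensityScanResult", function(object) {
  cat("DensityScanResult:", length(object@densities), "densities x",
      object@nReps, "replicates\n")
  h <- tapply(object@estimates$h2, object@estimates$density, mean,
              na.rm = TRUE)
  g <- tapply(object@grmCorrelations$correlation,
              object@grmCorrelations$density, mean)
  for (d in as.character(sort(object@densities)))
    cat(sprintf("  %8s markers: mean h2 %.4f, mean GRM correlation %.4f\n",
                d, h[d], g[d]))
})

#' Marker-density subsampling experiment
#'
#' For each density and replicate, draws a random marker subset, builds the
#' GRM, estimates heritability per time point with the univariate model and
#' (optionally) the cross-validation accuracy, then computes all pairwise
#' GRM correlations among the replicates of that density (30 replicates
#' give choose(30, 2) = 435 pairs). Per-replicate seeds are derived
#' deterministically from `baseSeed` and recorded.
#'
#' @param geno a [GenotypeMatrix-class] (the full panel).
#' @param pheno a [PhenotypeTable-class]
#' @param trait trait name.
#' @param densities marker counts to scan; each must not exceed the panel.
#' @param nReps replicates per density (default 30).
#' @param baseSeed base seed; replicate seeds are `baseSeed + 10007*densityIndex + rep`.
#' @param doCV also run uvLMM cross-validation per replicate (default TRUE).
#' @param nFolds folds for the CV (default 10).
#' @return a [DensityScanResult-class]
#' @export
densityScan <- function(geno, pheno, trait, densities, nReps = 30,
                        baseSeed = 1, doCV = TRUE, nFolds = 10) {
  stopifnot(is(geno, "GenotypeMatrix"))
  densities <- sort(as.numeric(densities))
  if (max(densities) > nMarkers(geno))
    stop("largest density exceeds the available markers")
  times <- pheno@times
  est <- list()
  gcorr <- list()
  for (di in seq_along(densities)) {
    d <- densities[di]
    triangles <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      seed <- as.integer((baseSeed + 10007 * di + r) %% .Machine$integer.max)
      sub <- subsampleMarkers(geno, d, seed = seed)
      grm <- vanRadenGRM(sub)
      triangles[[r]] <- grmMatrix(grm)[upper.tri(grmMatrix(grm), diag = TRUE)]
      accs <- rep(NA_real_, length(times))
      if (doCV) {
        cv <- tryCatch(
          runCV(grm, pheno, trait, "uvLMM", makeFolds(individualIds(grm),
                                                      nFolds, seed)),
          error = function(e) NULL)
        if (!is.null(cv)) accs <- as.numeric(meanAccuracy(cv))
      }
      for (ti in seq_along(times)) {
        fit <- tryCatch(fitUvLMM(grm, pheno, trait, times[ti]),
                        error = function(e) NULL)
        est[[length(est) + 1]] <- data.frame(
          density = d, rep = r, time = times[ti],
          h2 = if (is.null(fit)) NA_real_ else heritability(fit),
          accuracy = accs[ti], seed = seed,
          converged = !is.null(fit) && converged(fit))
      }
    }
    pairs <- which(upper.tri(matrix(0, nReps, nReps)), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      gcorr[[length(gcorr) + 1]] <- data.frame(
        density = d, rep1 = i, rep2 = j,
        correlation = cor(triangles[[i]], triangles[[j]]))
    }
  }
  emptyCorr <- data.frame(density = numeric(0), rep1 = integer(0),
                          rep2 = integer(0), correlation = numeric(0))
  new("DensityScanResult", estimates = do.call(rbind, est),
      grmCorrelations = if (length(gcorr)) do.call(rbind, gcorr) else emptyCorr,
      densities = densities, nReps = as.integer(nReps))
}

#' Compare two sets of replicate accuracies
#'
#' Two-sample t-test between replicate accuracies from two experimental arms
#' (different marker densities or different models). Welch's unequal-variance
#' form by default; Student's pooled form via `welch = FALSE`. Degenerate
#' inputs (both groups constant) return `p = 1` when the means are equal and
#' `p = 0` otherwise, by convention.
#'
#' @param a,b numeric vectors of replicate accuracies (at least 2 each).
#' @param welch use Welch's correction (default TRUE).
#' @return a list with `t`, `p` (two-sided), and `df`.
#' @export
compareAccuracies <- function(a, b, welch = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
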