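#' Build a VanRaden genomic relationship matrix
#'
#' Method 1 (the default, the usual ratio form):
#' `G = W W' / (2 sum_k p_k (1 - p_k))` with `W` the dosage matrix centred by
#' twice the in-sample allele frequencies. Method 2 scales each centred
#' column by `sqrt(2 p_k (1 - p_k))` and divides by the marker count.
#' Missing dosages are mean-imputed (twice the allele frequency) before
#' centring.
#'
#' @param g a [GenotypeMatrix-class]
#' @param method `"vanraden1"` (default) or `"vanraden2"`.
#' @param onMonomorphic `"drop"` (default): silently drop markers with zero
#'   in-sample variance; `"error"`: stop when any is present.
#' @return a [GRM-class]
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("m1", "m2")))
#' grmMatrix(vanRadenGRM(GenotypeMatrix(d)))  # [[2, -2], [-2, 2]]
#' @export
vanRadenGRM <- function(g, method = c("vanraden1", "vanraden2"),
                        onMonomorphic = c("drop", "error")) {
  method <- match.arg(method)
  onMonomorphic <- match.arg(onMonomorphic)
  stopifnot(is(g, "GenotypeMatrix"))
  g <- imputeMissing(g)
  p <- alleleFreq(g)
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    if (onMonomorphic == "error")
      stop(sum(mono), " monomorphic marker(s); drop them or pass onMonomorphic = 'drop'")
    if (all(mono)) stop("all markers are monomorphic: GRM denominator is zero")
    g <- g[, which(!mono)]
    p <- p[!mono]
  }
  W <- sweep(dosages(g), 2, 2 * p)
  het <- 2 * p * (1 - p)
  if (method == "vanraden1") {
    denom <- sum(het)
    G <- tcrossprod(W) / denom
  } else {
    W <- sweep(W, 2, sqrt(het), "/")
    denom <- ncol(W)
    G <- tcrossprod(W) / denom
  }
  G <- (G + t(G)) / 2
  new("GRM", mat = G, nMarkersUsed = ncol(W), denom = denom)
}

#' Pearson correlation between two GRMs
#'
#' Correlates the vectorized upper triangles (including the diagonal by
#' default; the diagonal carries the self-relationship sampling noise).
#'
#' @param a,b [GRM-class] objects over the same individuals in the same order.
#' @param includeDiagonal include the diagonal entries (default TRUE).
#' @return Pearson correlation in \[-1, 1\].
#' @export
grmCorrelation <- function(a, b, includeDiagonal = TRUE) {
  stopifnot(is(a, "GRM"), is(b, "GRM"))
  if (!identical(individualIds(a), individualIds(b)))
    stop("GRMs cover different individuals (or a different order)")
  keep <- upper.tri(grmMatrix(a), diag = includeDiagonal)
  stats::cor(grmMatrix(a)[keep], grmMatrix(b)[keep])
}

#' Stabilize a GRM by a diagonal shift
#'
#' Adds `epsilon` to the diagonal, lifting every eigenvalue by `epsilon`.
#' A GRM built with in-sample frequencies is singular (its rows sum to
#' zero), so downstream REML uses a stabilized copy whenever an inverse or
#' Cholesky factor is needed.
#'
#' @param a a [GRM-class]
#' @param epsilon non-negative shift, default 1e-6.
#' @return a [GRM-class]
#' @export
stabilizeGRM <- function(a, epsilon = 1e-6) {
  stopifnot(is(a, "GRM"), epsilon >= 0)
  if (epsilon == 0) return(a)
  m <- grmMatrix(a)
  diag(m) <- diag(m) + epsilon
  new("GRM", mat = m, nMarkersUsed = a@nMarkersUsed, denom = a@denom)
}

#' Write a GRM to disk
#'
#' `format = "gcta"` writes the GCTA binary layout: `prefix.grm.bin`
#' (lower triangle incl. diagonal, single-precision, row by row),
#' `prefix.grm.id` (family and individual id) and `prefix.grm.N.bin`
#' (markers per pair, here constant). `format = "csv"` writes the full
#' matrix with ids, for small n.
#'
#' @param a a [GRM-class]
#' @param prefix output prefix (gcta) or file path (csv).
#' @param format `"gcta"` or `"csv"`.
#' @return the prefix, invisibly.
#' @export
writeGRM <- function(a, prefix, format = c("gcta", "csv")) {
  format <- match.arg(format)
  m <- grmMatrix(a)
  ids <- individualIds(a)
  if (format == "csv") {
    df <- data.frame(id = ids, m, check.names = FALSE)
    write.csv(df, prefix, row.names = FALSE, quote = FALSE)
    return(invisible(prefix))
  }
  n <- nrow(m)
  ## GCTA order: for each i, entries (i, 1..i)
  lower <- unlist(lapply(seq_len(n), function(i) m[i, 1:i]), use.names = FALSE)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(a@nMarkersUsed), n * (n + 1) / 2), con, size = 4)
  close(con)
  write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
              row.names = FALSE, col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GRM written by [writeGRM()]
#'
#' @param prefix prefix (gcta) or file path (csv).
#' @param format `"gcta"` or `"csv"`.
#' @return a [GRM-class]
#' @export
readGRM <- function(prefix, format = c("gcta", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(prefix, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- colnames(m) <- as.character(df[[1]])
    m <- (m + t(m)) / 2
    return(new("GRM", mat = m, nMarkersUsed = NA_integer_, denom = NA_real_))
  }
  ids <- read.table(paste0(prefix, ".grm.id"), stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric",
                  n = n * (n + 1) / 2, size = 4)
  Ns <- readBin(paste0(prefix, ".grm.N.bin"), "numeric",
                n = n * (n + 1) / 2, size = 4)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  k <- 1L
  for (i in seq_len(n)) {
    m[i, 1:i] <- vals[k:(k + i - 1L)]
    k <- k + i
  }
  m <- m + t(m) - diag(diag(m))
  new("GRM", mat = m, nMarkersUsed = as.integer(round(Ns[1])),
      denom = NA_real_)
}
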