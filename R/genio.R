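#' @importFrom utils read.csv write.csv read.table write.table
#' @importFrom stats rbinom runif rnorm setNames
NULL

## Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Subset a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class]
#' @param i individual indices or ids
#' @param j marker indices or ids
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  if (is.character(j)) j <- match(j, colnames(d))
  GenotypeMatrix(d[i, j, drop = FALSE], chrom = x@chrom[j], pos = x@pos[j])
})

# ---------------------------------------------------------------------------
# Readers / writers

#' Read genotypes from PLINK bed/bim/fam, VCF, or a dosage CSV
#'
#' Dosages are continuous in \[0, 2\] and count the alternate (A1) allele.
#' From a VCF the `DS` FORMAT field is preferred when present, otherwise
#' hard `GT` calls are counted. Missing genotypes become `NA`, never 0.
#'
#' @param path file path. For PLINK, either the `.bed` file or the common
#'   prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @param format `"auto"` (by extension), `"plink-bed"`, `"vcf"` or
#'   `"matrix-csv"`. The CSV dialect has a header row of marker ids and the
#'   individual id in the first column.
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypes <- function(path, format = c("auto", "plink-bed", "vcf", "matrix-csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink-bed"
    else if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (grepl("\\.csv$", path)) "matrix-csv"
    else stop("cannot infer genotype format from path: ", path)
  }
  switch(format,
         "plink-bed" = readPlinkBed(path),
         "vcf" = readVcfDosages(path),
         "matrix-csv" = readMatrixCsv(path))
}

readMatrixCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix-csv needs an id column plus at least one marker: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric dosage entries in ", path)
  rownames(m) <- ids
  GenotypeMatrix(m)
}

## PLINK .bed 2-bit codes (SNP-major): 00 = hom A1 (dosage 2), 01 = missing,
## 10 = het, 11 = hom A2 (dosage 0).
plinkByteLookup <- function() {
  codes <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  L <- matrix(NA_real_, 256, 4)
  b <- 0:255
  for (k in 1:4) L[, k] <- codes[as.character(b %/% 4^(k - 1) %% 4)]
  L
}

readPlinkBed <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bimd <- read.table(bim, stringsAsFactors = FALSE)
  famd <- read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famd); m <- nrow(bimd)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed)
  bpm <- ceiling(n / 4)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpm, ncol = m)
  L <- plinkByteLookup()
  d <- matrix(NA_real_, n, m)
  idx <- rep(seq_len(bpm), each = 4)[seq_len(n)]
  slot4 <- rep(1:4, times = bpm)[seq_len(n)]
  for (k in 1:4) {
    rows <- which(slot4 == k)
    if (length(rows)) d[rows, ] <- L[body[idx[rows], , drop = FALSE] + 1L, k]
  }
  rownames(d) <- as.character(famd[[2]])
  colnames(d) <- as.character(bimd[[2]])
  if (anyDuplicated(rownames(d))) stop("duplicate individual ids in ", fam)
  if (anyDuplicated(colnames(d))) stop("duplicate marker ids in ", bim)
  GenotypeMatrix(d, chrom = as.character(bimd[[1]]), pos = as.integer(bimd[[4]]))
}

readVcfDosages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, 1]
  hasDS <- all(grepl("DS", fmt))
  if (hasDS) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(s) {
      a <- strsplit(gsub("\\|", "/", s), "/")
      vapply(a, function(x) {
        if (any(x == "." | is.na(x))) NA_real_ else sum(x != "0")
      }, numeric(1))
    }
    d <- apply(gt, 2, cnt)
    dim(d) <- dim(gt); dimnames(d) <- dimnames(gt)
  }
  d <- t(d)  # vcfR gives markers x samples
  ids <- rownames(d)
  mk <- colnames(d)
  if (is.null(mk) || any(is.na(mk)) || anyDuplicated(mk))
    mk <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = ":")
  colnames(d) <- mk
  GenotypeMatrix(d, chrom = as.character(v@fix[, "CHROM"]),
                 pos = as.integer(v@fix[, "POS"]))
}

#' Write genotypes to PLINK bed/bim/fam or dosage CSV
#'
#' PLINK output stores hard calls; non-integer dosages are rounded with a
#' warning. Alleles are written as A1 = "A" (the counted allele) and
#' A2 = "B".
#'
#' @param g a [GenotypeMatrix-class]
#' @param prefix output path; for PLINK the prefix of the triplet, for CSV
#'   the full file name.
#' @param format `"plink-bed"` or `"matrix-csv"`.
#' @return the prefix, invisibly.
#' @export
writeGenotypes <- function(g, prefix, format = c("plink-bed", "matrix-csv")) {
  format <- match.arg(format)
  d <- dosages(g)
  if (format == "matrix-csv") {
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    write.csv(df, prefix, row.names = FALSE, quote = FALSE)
    return(invisible(prefix))
  }
  if (any(abs(d - round(d)) > 1e-8, na.rm = TRUE)) {
    warning("non-integer dosages rounded to hard calls for PLINK output")
  }
  d <- round(d)
  n <- nrow(d); m <- ncol(d)
  ## dosage -> 2-bit code
  code <- matrix(1L, n, m)          # 01 = missing
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  bpm <- ceiling(n / 4)
  pad <- bpm * 4 - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))
  w <- 4^(0:3)
  bytes <- code[seq(1, bpm * 4, 4), , drop = FALSE] * w[1] +
    code[seq(2, bpm * 4, 4), , drop = FALSE] * w[2] +
    code[seq(3, bpm * 4, 4), , drop = FALSE] * w[3] +
    code[seq(4, bpm * 4, 4), , drop = FALSE] * w[4]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  bim <- data.frame(chromosomes(g), markerIds(g), 0, positions(g), "A", "B")
  write.table(bim, paste0(prefix, ".bim"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  fam <- data.frame(rownames(d), rownames(d), 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a phenotype CSV
#'
#' Expected columns: `id`, `sex`, `batch`, then one `<trait>_<time>` column
#' per trait and time point. Empty cells are missing records.
#'
#' @param path CSV file path.
#' @param times time points; default inferred from the column names.
#' @return a [PhenotypeTable-class]
#' @export
readPhenotypes <- function(path, times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "sex", "batch")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns id, sex, batch: ", path)
  vcols <- setdiff(names(df), need)
  if (is.null(times)) {
    times <- sort(unique(as.numeric(sub("^.*_", "", vcols))))
    if (any(is.na(times))) stop("cannot infer time points from columns in ", path)
  }
  v <- as.matrix(df[, vcols, drop = FALSE])
  storage.mode(v) <- "double"
  PhenotypeTable(df$id, df$sex, df$batch, v, times = times)
}

#' Write a phenotype table to CSV
#'
#' @param p a [PhenotypeTable-class]
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePhenotypes <- function(p, path) {
  df <- data.frame(id = p@ids, sex = as.character(p@sex),
                   batch = as.character(p@batch), p@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# QC

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact test conditional on the allele counts: the p-value is the total
#' probability of all heterozygote counts that are no more probable than the
#' observed one. Intended for hard genotype calls.
#'
#' @param nAA,nAa,naa non-negative genotype counts (vectorized).
#' @return p-value(s) in (0, 1\].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- length(nAA)
  stopifnot(length(nAa) == n, length(naa) == n)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- hweExactOne(nAA[i], nAa[i], naa[i])
  out
}

hweExactOne <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0) || any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    stop("genotype counts must be non-negative integers")
  n <- nAA + nAa + naa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  nMinor <- min(nA, na)
  ## heterozygote counts share the parity of the minor allele count
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  ## log P(het | n, nA) up to a constant: 2^het / (hom1! het! hom2!)
  logp <- hets * log(2) - lgamma((nMinor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((max(nA, na) - hets) / 2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  if (is.na(obs)) stop("impossible genotype configuration")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Marker quality control
#'
#' Retains exactly the markers with minor allele frequency strictly above
#' `mafMin`, missing-genotype fraction strictly below `missingRateMax`, and
#' Hardy-Weinberg exact-test p-value strictly above `hwePMin` (the HWE test
#' rounds dosages to hard calls). Comparisons are strict on purpose.
#'
#' @param g a [GenotypeMatrix-class]
#' @param thresholds a [QCThresholds-class]; default `qcThresholds()`.
#' @return a list with `genotypes` (the filtered [GenotypeMatrix-class], or
#'   `NULL` when nothing survives) and `report`, a data.frame with one row
#'   per input marker: `maf`, `missingRate`, `hweP`, `pass`, and the first
#'   failing criterion in `reason`.
#' @export
qcFilter <- function(g, thresholds = qcThresholds()) {
  stopifnot(is(g, "GenotypeMatrix"), is(thresholds, "QCThresholds"))
  d <- dosages(g)
  p <- alleleFreq(g)
  maf <- pmin(p, 1 - p)
  missRate <- colMeans(is.na(d))
  hard <- round(d)
  nAA <- colSums(hard == 2, na.rm = TRUE)
  nAa <- colSums(hard == 1, na.rm = TRUE)
  naa <- colSums(hard == 0, na.rm = TRUE)
  ## test each distinct count triple once
  key <- paste(nAA, nAa, naa)
  uk <- !duplicated(key)
  hweU <- hweExactTest(nAA[uk], nAa[uk], naa[uk])
  hweP <- hweU[match(key, key[uk])]
  pass <- maf > thresholds@mafMin &
    missRate < thresholds@missingRateMax &
    hweP > thresholds@hwePMin
  reason <- rep(NA_character_, length(pass))
  reason[!(maf > thresholds@mafMin)] <- "maf"
  reason[is.na(reason) & !(missRate < thresholds@missingRateMax)] <- "missing_rate"
  reason[is.na(reason) & !(hweP > thresholds@hwePMin)] <- "hwe"
  report <- data.frame(marker = markerIds(g), maf = maf,
                       missingRate = missRate, hweP = hweP, pass = pass,
                       reason = reason, row.names = NULL)
  if (!any(pass)) {
    warning("all markers removed by QC")
    return(list(genotypes = NULL, report = report))
  }
  list(genotypes = g[, which(pass)], report = report)
}

#' Random marker subsampling
#'
#' Draws exactly `k` distinct markers uniformly without replacement,
#' preserving their original order. Deterministic for a fixed seed.
#'
#' @param g a [GenotypeMatrix-class]
#' @param k number of markers to keep; must not exceed `nMarkers(g)`.
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @return a [GenotypeMatrix-class] with `k` markers.
#' @export
subsampleMarkers <- function(g, k, seed = NULL) {
  m <- nMarkers(g)
  if (k > m) stop("k (", k, ") exceeds the number of markers (", m, ")")
  if (k < 1) stop("k must be positive")
  idx <- withSeed(seed, sort(sample.int(m, k)))
  g[, idx]
}

#' Mean-impute missing dosages
#'
#' Replaces each missing dosage with twice the in-sample allele frequency of
#' its marker. Applied immediately before relationship-matrix construction,
#' never before QC.
#'
#' @param g a [GenotypeMatrix-class]
#' @return a [GenotypeMatrix-class] without missing values.
#' @export
imputeMissing <- function(g) {
  d <- dosages(g)
  if (!anyNA(d)) return(g)
  p2 <- 2 * alleleFreq(g)
  na <- which(is.na(d), arr.ind = TRUE)
  d[na] <- p2[na[, 2]]
  GenotypeMatrix(d, chrom = g@chrom, pos = g@pos)
}
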