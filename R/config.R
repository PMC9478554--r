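## Schema of the YAML run configuration used by the command-line driver
## (inst/scripts/gsrun.R). Nested named lists: NULL marks a required group,
## functions validate leaves.
runConfigSchema <- function() {
  num <- function(x) is.numeric(x) && all(is.finite(x))
  chr <- function(x) is.character(x) && length(x) >= 1
  lgl <- function(x) is.logical(x) && length(x) == 1
  list(
    seed = num,
    outDir = chr,
    paths = list(genotypes = chr, phenotypes = chr, grm = chr),
    simulate = list(nIndividuals = num, nMarkers = num, nChromosomes = num,
                    ldRho = num, mafLow = num, mafHigh = num, nQtl = num,
                    h2 = num, geneticCorr = num, mean = num,
                    sexEffect = num, batchEffects = num, traitName = chr),
    qc = list(mafMin = num, missingRateMax = num, hwePMin = num),
    experiment = list(densities = num, nReps = num, models = chr,
                      traits = chr, nFolds = num, doCV = lgl),
    verbose = lgl
  )
}

#' Validate a run configuration
#'
#' Checks a (nested) configuration list against the published schema of the
#' command-line driver: unknown keys are rejected and every provided leaf
#' must have the expected type. Returns the config invisibly when valid,
#' otherwise stops with the path of the offending key.
#'
#' @param config a named list, typically from `yaml::read_yaml()`.
#' @return the validated config, invisibly.
#' @export
validateRunConfig <- function(config) {
  check <- function(cfg, schema, path) {
    if (!is.list(cfg) || (length(cfg) && is.null(names(cfg))))
      stop("config section must be a named list: ", path)
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown))
      stop("unknown config key: ", paste0(path, "/", unknown[1]))
    for (k in names(cfg)) {
      here <- paste0(path, "/", k)
      sc <- schema[[k]]
      if (is.function(sc)) {
        if (!sc(cfg[[k]])) stop("invalid value for config key: ", here)
      } else {
        check(cfg[[k]], sc, here)
      }
    }
  }
  check(config, runConfigSchema(), "")
  invisible(config)
}

#' Serialize a REML fit to JSON
#'
#' Documented layout: `model` ("uv" or "mv"), `varComponents`,
#' `heritability` (with `se` for univariate fits), `geneticCorrelation`
#' (multivariate), `beta`, `logLik`, `iterations`, `converged`, and the
#' convergence `trace` for multivariate fits. GEBVs are written separately
#' by [writeGEBV()].
#'
#' @param fit a [UvFit-class] or [MvFit-class]
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeFit <- function(fit, path) {
  out <- if (is(fit, "UvFit")) {
    list(model = "uv",
         varComponents = list(sigma2u = fit@sigma2u, sigma2e = fit@sigma2e),
         heritability = list(h2 = fit@h2, se = fit@seH2,
                             boundary = fit@boundary),
         beta = as.list(fit@beta), logLik = fit@loglik,
         iterations = fit@nIterations, converged = fit@converged)
  } else {
    list(model = "mv",
         varComponents = list(SigmaU = fit@SigmaU, SigmaE = fit@SigmaE),
         heritability = as.list(setNames(fit@h2, colnames(fit@gebv))),
         geneticCorrelation = fit@geneticCorr,
         beta = as.list(fit@beta), logLik = fit@loglik,
         iterations = fit@nIterations, converged = fit@converged,
         trace = fit@loglikTrace)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write GEBVs to CSV
#'
#' @param fit a [UvFit-class] or [MvFit-class]
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeGEBV <- function(fit, path) {
  g <- gebv(fit)
  df <- if (is.matrix(g)) data.frame(id = rownames(g), g, check.names = FALSE)
  else data.frame(id = names(g), gebv = unname(g))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
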