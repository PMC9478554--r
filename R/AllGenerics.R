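#' @import methods
NULL

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @export
setGeneric("nMarkersUsed", function(x) standardGeneric("nMarkersUsed"))

#' @export
setGeneric("traitValues", function(x, trait) standardGeneric("traitValues"))

#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @export
setGeneric("geneticCorrelation", function(x) standardGeneric("geneticCorrelation"))

#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @export
setGeneric("logLikREML", function(x) standardGeneric("logLikREML"))

#' Predict genomic breeding values for a set of individuals
#'
#' @param fit a fitted model ([UvFit-class] or [MvFit-class])
#' @param grm the [GRM-class] the model was fitted with
#' @param targetIds character vector of individual ids, a subset of the GRM ids
#' @return for a univariate fit, a named numeric vector; for a multivariate
#'   fit, a matrix with one column per time point.
#' @export
setGeneric("predictGEBV", function(fit, grm, targetIds) standardGeneric("predictGEBV"))

#' @export
setGeneric("meanAccuracy", function(x, ...) standardGeneric("meanAccuracy"))
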