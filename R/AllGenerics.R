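#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @export
setGeneric("nLocations", function(x) standardGeneric("nLocations"))

#' @export
setGeneric("trackTimes", function(x, absolute = FALSE) standardGeneric("trackTimes"))

#' @export
setGeneric("trackCoords", function(x) standardGeneric("trackCoords"))

#' @export
setGeneric("timeLags", function(x) standardGeneric("timeLags"))

#' @export
setGeneric("locationCovariates", function(x) standardGeneric("locationCovariates"))

#' @export
setGeneric("segmentCovariates", function(x) standardGeneric("segmentCovariates"))

#' @export
setGeneric("computeIncrements", function(traj) standardGeneric("computeIncrements"))

#' @export
setGeneric("nBasis", function(basis) standardGeneric("nBasis"))

#' @export
setGeneric("evalSpline", function(basis, t) standardGeneric("evalSpline"))

#' @export
setGeneric("segmentAverageSpline", function(basis, tStart, tEnd)
  standardGeneric("segmentAverageSpline"))

#' @export
setGeneric("movementMatrix", function(design) standardGeneric("movementMatrix"))

#' @export
setGeneric("errorMatrix", function(design) standardGeneric("errorMatrix"))

#' @export
setGeneric("splitRhat", function(chains) standardGeneric("splitRhat"))

#' @export
setGeneric("posteriorIntervals", function(chains, levels = c(0.5, 0.95))
  standardGeneric("posteriorIntervals"))

#' @export
setGeneric("posteriorDraws", function(chains, pooled = TRUE)
  standardGeneric("posteriorDraws"))

#' @export
setGeneric("coefficients", function(object, ...) standardGeneric("coefficients"))

#' @export
setGeneric("logLik", function(object, ...) standardGeneric("logLik"))

#' @export
setGeneric("aic", function(object) standardGeneric("aic"))
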