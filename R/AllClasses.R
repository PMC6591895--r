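## Central S4 classes. Validity methods enforce the model's structural
## invariants so downstream numerical code can assume well-formed objects.

.emptyDf <- function(n) {
  structure(list(), class = "data.frame", row.names = .set_row_names(n))
}

#' Trajectory: an ordered planar track with covariate tables
#'
#' A trajectory of \eqn{n+1} locations observed at strictly increasing times
#' in a planar metric projection (coordinates in metres). Covariates of the
#' location error live in a table with one row per location; covariates of
#' the movement live in a table with one row per segment (the interval
#' between two consecutive locations) and are taken to represent the whole
#' interval.
#'
#' Internally times are stored as seconds since the first fix
#' (double precision); the absolute time of the first fix is kept in
#' `timeOrigin` so that time-of-day phases remain available for periodic
#' covariates.
#'
#' @slot times numeric, seconds since track start, strictly increasing,
#'   first element 0, length \eqn{n+1}.
#' @slot coords numeric matrix, \eqn{(n+1) \times 2}, metres.
#' @slot timeOrigin numeric scalar, absolute time (seconds, e.g. since epoch)
#'   of the first location; 0 when the input times were already relative.
#' @slot locationCovariates data.frame with \eqn{n+1} rows.
#' @slot segmentCovariates data.frame with \eqn{n} rows.
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    coords = "matrix",
    timeOrigin = "numeric",
    locationCovariates = "data.frame",
    segmentCovariates = "data.frame"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  np1 <- length(object@times)
  if (np1 < 2L) msg <- c(msg, "a trajectory needs at least 2 locations (n >= 1)")
  if (nrow(object@coords) != np1 || ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be an (n+1) x 2 matrix")
  if (any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (np1 >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing (all tau_i > 0)")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@timeOrigin) != 1L || !is.finite(object@timeOrigin))
    msg <- c(msg, "timeOrigin must be a finite scalar")
  if (nrow(object@locationCovariates) != np1)
    msg <- c(msg, "locationCovariates must have one row per location (n+1)")
  if (nrow(object@segmentCovariates) != np1 - 1L)
    msg <- c(msg, "segmentCovariates must have one row per segment (n)")
  if (anyNA(object@locationCovariates) || anyNA(object@segmentCovariates))
    msg <- c(msg, "missing covariate values are not allowed")
  if (length(msg)) msg else TRUE
})

#' Increments: coordinate differences between consecutive locations
#'
#' @slot deltas numeric matrix, \eqn{n \times 2}: componentwise differences
#'   of consecutive observed coordinates.
#' @slot taus numeric, \eqn{n} positive time lags (seconds).
#' @export
setClass("Increments",
  representation(deltas = "matrix", taus = "numeric")
)

setValidity("Increments", function(object) {
  if (nrow(object@deltas) != length(object@taus))
    return("deltas and taus must have matching length n")
  if (any(object@taus <= 0)) return("all time lags must be positive")
  TRUE
})

#' SplineBasis: a circular (periodic) cubic B-spline basis
#'
#' Cubic B-splines on a circle of circumference `period`, so that daily (or
#' other periodic) activity curves wrap around without an artificial cut
#' point. With K distinct knots the basis has exactly K functions; they are
#' non-negative and sum to one at every phase (partition of unity), so the
#' basis contains the constant function and absorbs an intercept.
#'
#' @slot period positive scalar, seconds (default one day, 86400).
#' @slot knots K increasing knot positions in `[0, period)`; K >= 4.
#'   Non-uniform placement is how observation gaps (e.g. tags off at night)
#'   are handled: knots are concentrated where data exist.
#' @slot degree spline degree, fixed at 3 (cubic).
#' @export
setClass("SplineBasis",
  representation(period = "numeric", knots = "numeric", degree = "integer")
)

setValidity("SplineBasis", function(object) {
  msg <- character()
  if (length(object@period) != 1L || object@period <= 0)
    msg <- c(msg, "period must be a positive scalar")
  if (length(object@knots) < 4L)
    msg <- c(msg, "a cubic circular basis needs at least 4 knots")
  if (is.unsorted(object@knots, strictly = TRUE))
    msg <- c(msg, "knots must be strictly increasing")
  if (any(object@knots < 0) || any(object@knots >= object@period))
    msg <- c(msg, "knots must lie in [0, period)")
  if (object@degree != 3L)
    msg <- c(msg, "only cubic (degree 3) bases are supported")
  if (length(msg)) msg else TRUE
})

#' DesignSpec: the model formula of a BBCM fit
#'
#' Two lists of term descriptors, one generating the per-segment movement
#' variances sigma^2 (from segment covariates) and one the per-location
#' error variances delta^2 (from location covariates). Terms are built with
#' [interceptTerm()], [linearTerm()], [factorTerm()] and [splineTerm()].
#'
#' @slot movementTerms list of term descriptors for the sigma^2 side.
#' @slot errorTerms list of term descriptors for the delta^2 side.
#' @export
setClass("DesignSpec",
  representation(movementTerms = "list", errorTerms = "list")
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  for (side in c("movementTerms", "errorTerms")) {
    terms <- slot(object, side)
    if (length(terms) < 1L)
      msg <- c(msg, paste(side, "needs at least one term"))
    if (!all(vapply(terms, inherits, TRUE, what = "bbcmTerm")))
      msg <- c(msg, paste(side, "must be a list of bbcm term descriptors"))
    hasFreeIntercept <- any(vapply(terms, function(t) t$type == "intercept", TRUE))
    hasFullSpline <- any(vapply(terms, function(t)
      t$type == "spline" && !isTRUE(t$separateConstant), TRUE))
    if (hasFreeIntercept && hasFullSpline)
      msg <- c(msg, paste0(
        side, ": a full circular spline already contains the constant; ",
        "combining it with a free intercept gives a model with multiple ",
        "solutions. Use splineTerm(..., separateConstant = TRUE) or drop ",
        "the intercept."))
  }
  if (length(msg)) msg else TRUE
})

#' VarianceDesign: realized design matrices for sigma^2 and delta^2
#'
#' The result of [buildDesign()]: a numeric design matrix per side, the
#' column type bookkeeping needed for scaling and back-transformation, and
#' the spline basis (if any) for reconstructing fitted activity curves.
#'
#' @slot movementMatrix n x m_sigma matrix (rows = segments).
#' @slot errorMatrix (n+1) x m_delta matrix (rows = locations).
#' @slot movementTypes,errorTypes character per column:
#'   `"intercept"`, `"contrast"`, `"linear"` or `"spline"`.
#' @slot scaling list with elements `movement` and `error`; each is either
#'   NULL or a list of per-column `center` and `scale` vectors recording the
#'   transform applied by [scaleColumns()].
#' @slot movementBasis,errorBasis the [SplineBasis-class] behind any spline
#'   columns on that side, or NULL.
#' @export
setClass("VarianceDesign",
  representation(
    movementMatrix = "matrix",
    errorMatrix = "matrix",
    movementTypes = "character",
    errorTypes = "character",
    scaling = "list",
    movementBasis = "ANY",
    errorBasis = "ANY"
  )
)

setValidity("VarianceDesign", function(object) {
  msg <- character()
  if (nrow(object@errorMatrix) != nrow(object@movementMatrix) + 1L)
    msg <- c(msg, "errorMatrix must have exactly one more row than movementMatrix")
  if (ncol(object@movementMatrix) != length(object@movementTypes))
    msg <- c(msg, "movementTypes must label every movement column")
  if (ncol(object@errorMatrix) != length(object@errorTypes))
    msg <- c(msg, "errorTypes must label every error column")
  if (any(!is.finite(object@movementMatrix)) || any(!is.finite(object@errorMatrix)))
    msg <- c(msg, "design matrices must be finite")
  if (length(msg)) msg else TRUE
})

#' TribandedCovariance: a symmetric tridiagonal covariance matrix
#'
#' Stored as its diagonal and (single) off-diagonal band; never densified by
#' package code. Built from positive sigma^2/delta^2 vectors it is positive
#' definite, which the LDL' pivots verify at evaluation time.
#'
#' @slot diag k positive reals.
#' @slot offdiag k-1 reals.
#' @export
setClass("TribandedCovariance",
  representation(diag = "numeric", offdiag = "numeric")
)

setValidity("TribandedCovariance", function(object) {
  if (length(object@offdiag) != length(object@diag) - 1L)
    return("offdiag must be one element shorter than diag")
  if (any(!is.finite(object@diag)) || any(!is.finite(object@offdiag)))
    return("bands must be finite")
  TRUE
})

#' BbcmParams: a parameter vector of the model
#'
#' @slot betaSigma coefficients generating the movement variances sigma^2.
#' @slot betaDelta coefficients generating the error variances delta^2.
#' @slot gamma the trajectory origin (x, y), or numeric(0) when the origin
#'   is treated as known/fixed at the first observed location.
#' @export
setClass("BbcmParams",
  representation(betaSigma = "numeric", betaDelta = "numeric", gamma = "numeric")
)

setValidity("BbcmParams", function(object) {
  if (!length(object@gamma) %in% c(0L, 2L))
    return("gamma must be empty or an (x, y) pair")
  if (anyNA(object@betaSigma) || anyNA(object@betaDelta) || anyNA(object@gamma))
    return("parameters must not contain NA")
  TRUE
})

#' FitResult: a maximum-likelihood fit
#'
#' @slot params point estimate, coefficients on the ORIGINAL covariate scale.
#' @slot parameterNames names matching the packed parameter vector.
#' @slot logLik maximized log-likelihood.
#' @slot aic 2k - 2 logLik, exactly.
#' @slot nParams k: all beta coefficients plus 2 when the origin is estimated.
#' @slot convergence optimizer convergence code (0 = converged).
#' @slot scaled whether covariate columns were scaled internally during
#'   optimization (estimates are always back-transformed).
#' @slot fingerprint summary statistics of the fitted trajectory, used to
#'   refuse AIC comparisons across different data.
#' @slot modelLabel free-text label used in comparison tables.
#' @export
setClass("FitResult",
  representation(
    params = "BbcmParams",
    parameterNames = "character",
    logLik = "numeric",
    aic = "numeric",
    nParams = "integer",
    convergence = "integer",
    scaled = "logical",
    fingerprint = "numeric",
    modelLabel = "character"
  )
)

setValidity("FitResult", function(object) {
  if (abs(object@aic - (2 * object@nParams - 2 * object@logLik)) > 1e-8)
    return("aic must equal 2k - 2 logLik")
  TRUE
})

#' PosteriorChains: post-warmup, thinned MCMC draws
#'
#' @slot draws array `[iteration, chain, parameter]` of retained draws, on
#'   the original covariate scale.
#' @slot parameterNames parameter labels.
#' @slot warmup number of warmup iterations discarded per chain.
#' @slot thin thinning interval.
#' @slot seed RNG seed of the run (reproducibility record).
#' @slot acceptance post-warmup acceptance rate per chain.
#' @export
setClass("PosteriorChains",
  representation(
    draws = "array",
    parameterNames = "character",
    warmup = "integer",
    thin = "integer",
    seed = "numeric",
    acceptance = "numeric"
  )
)

setValidity("PosteriorChains", function(object) {
  d <- dim(object@draws)
  if (length(d) != 3L) return("draws must be [iteration, chain, parameter]")
  if (d[2] < 2L) return("at least 2 chains are required (for split R-hat)")
  if (d[3] != length(object@parameterNames))
    return("parameterNames must match the parameter dimension")
  TRUE
})

#' SimulationDesign: generating parameters of the validation simulator
#'
#' Defaults are the validation study conditions: three movement states with
#' occupancy probabilities (0.5, 0.2, 0.3) and diffusion rates
#' sigma^2 = (0.3, 0.8, 2) m^2/s, a continuous movement covariate sampled
#' uniformly on (0, 0.5) with slope 2; three location-error categories with
#' probabilities (0.25, 0.5, 0.25) and error variances (3, 3.9, 6) m^2, a
#' continuous error covariate on (-1, 1) with slope 0.4; inter-fix gaps of
#' 1 s plus a Gamma(shape 3, rate 0.1) draw (mean 31 s).
#'
#' @slot nLocations default number of locations to simulate.
#' @slot stateProbs,stateSigma2 movement-state probabilities and rates.
#' @slot movementCovRange,movementSlope uniform range and slope of the
#'   continuous movement covariate.
#' @slot errorCatProbs,errorCatDelta2 error-category probabilities and
#'   variances.
#' @slot errorCovRange,errorSlope uniform range and slope of the continuous
#'   error covariate.
#' @slot gapShape,gapRate,gapOffset gamma parameters and additive offset (s)
#'   of the inter-fix intervals.
#' @export
setClass("SimulationDesign",
  representation(
    nLocations = "integer",
    stateProbs = "numeric",
    stateSigma2 = "numeric",
    movementCovRange = "numeric",
    movementSlope = "numeric",
    errorCatProbs = "numeric",
    errorCatDelta2 = "numeric",
    errorCovRange = "numeric",
    errorSlope = "numeric",
    gapShape = "numeric",
    gapRate = "numeric",
    gapOffset = "numeric"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (abs(sum(object@stateProbs) - 1) > 1e-8 ||
      abs(sum(object@errorCatProbs) - 1) > 1e-8)
    msg <- c(msg, "state/category probabilities must sum to 1")
  if (any(object@stateSigma2 <= 0) || any(object@errorCatDelta2 <= 0))
    msg <- c(msg, "state sigma^2 and category delta^2 must be positive")
  if (length(object@stateProbs) != length(object@stateSigma2))
    msg <- c(msg, "one sigma^2 per movement state required")
  if (length(object@errorCatProbs) != length(object@errorCatDelta2))
    msg <- c(msg, "one delta^2 per error category required")
  ## positivity over the whole covariate range, not just in expectation
  if (min(object@stateSigma2) +
      object@movementSlope * min(object@movementCovRange) <= 0 ||
      min(object@stateSigma2) +
      object@movementSlope * max(object@movementCovRange) <= 0)
    msg <- c(msg, "movement design implies non-positive sigma^2 somewhere in range")
  if (min(object@errorCatDelta2) +
      object@errorSlope * min(object@errorCovRange) <= 0 ||
      min(object@errorCatDelta2) +
      object@errorSlope * max(object@errorCovRange) <= 0)
    msg <- c(msg, "error design implies non-positive delta^2 somewhere in range")
  if (object@gapShape <= 0 || object@gapRate <= 0 || object@gapOffset < 0)
    msg <- c(msg, "gap gamma parameters must be positive (offset non-negative)")
  if (length(msg)) msg else TRUE
})

#' SimulatedTrajectory: a trajectory plus the truth that generated it
#'
#' @slot trajectory the simulated [Trajectory-class] (observed, i.e.
#'   error-contaminated, positions; covariates attached).
#' @slot truth generating parameters coded exactly as [buildDesign()] codes
#'   the attached covariates (intercept + treatment contrasts), so fitted
#'   coefficients are directly comparable.
#' @slot sigma2,delta2 the realized per-segment and per-location variances.
#' @slot modelSpec the [DesignSpec-class] matching the truth coding.
#' @slot parameterNames labels of the packed truth vector.
#' @export
setClass("SimulatedTrajectory",
  representation(
    trajectory = "Trajectory",
    truth = "BbcmParams",
    sigma2 = "numeric",
    delta2 = "numeric",
    modelSpec = "DesignSpec",
    parameterNames = "character"
  )
)

#' UDGrid: a utilization distribution on a regular grid
#'
#' @slot x,y cell-centre coordinates (metres, regular spacing).
#' @slot mass matrix `[length(x), length(y)]` of cell probability masses,
#'   non-negative, summing to 1.
#' @slot cellSize scalar cell edge length (metres).
#' @export
setClass("UDGrid",
  representation(x = "numeric", y = "numeric", mass = "matrix",
                 cellSize = "numeric")
)

setValidity("UDGrid", function(object) {
  msg <- character()
  if (!all(dim(object@mass) == c(length(object@x), length(object@y))))
    msg <- c(msg, "mass must be a length(x) x length(y) matrix")
  if (any(object@mass < 0)) msg <- c(msg, "cell masses must be non-negative")
  if (abs(sum(object@mass) - 1) > 1e-6)
    msg <- c(msg, "cell masses must sum to 1 (within 1e-6)")
  if (length(msg)) msg else TRUE
})
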