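## trajectory_simulator: synthetic tracks with known generating parameters,
## matching the validation study conditions (heteroscedastic states and
## error categories, continuous drivers, gamma inter-fix gaps, periodic
## activity patterns).

#' Generating parameters for simulated validation trajectories
#'
#' See [SimulationDesign-class] for the meaning and the default study
#' conditions (three movement states, three error categories, continuous
#' covariates on both sides, gamma inter-fix gaps of mean 31 s).
#'
#' @param nLocations default track length (number of locations).
#' @param stateProbs,stateSigma2,movementCovRange,movementSlope movement side.
#' @param errorCatProbs,errorCatDelta2,errorCovRange,errorSlope error side.
#' @param gapShape,gapRate,gapOffset inter-fix interval model:
#'   `gapOffset + Gamma(gapShape, rate = gapRate)` seconds.
#' @return A validated [SimulationDesign-class].
#' @export
simulationDesign <- function(nLocations = 1000L,
                             stateProbs = c(0.5, 0.2, 0.3),
                             stateSigma2 = c(0.3, 0.8, 2),
                             movementCovRange = c(0, 0.5),
                             movementSlope = 2,
                             errorCatProbs = c(0.25, 0.5, 0.25),
                             errorCatDelta2 = c(3, 3.9, 6),
                             errorCovRange = c(-1, 1),
                             errorSlope = 0.4,
                             gapShape = 3, gapRate = 0.1, gapOffset = 1) {
  new("SimulationDesign",
      nLocations = as.integer(nLocations),
      stateProbs = stateProbs, stateSigma2 = stateSigma2,
      movementCovRange = movementCovRange, movementSlope = movementSlope,
      errorCatProbs = errorCatProbs, errorCatDelta2 = errorCatDelta2,
      errorCovRange = errorCovRange, errorSlope = errorSlope,
      gapShape = gapShape, gapRate = gapRate, gapOffset = gapOffset)
}

#' Simulate inter-fix time intervals
#'
#' Draws `tau_i = offset + Gamma(shape, rate)` seconds. With the default
#' shape 3 and rate 0.1 the mean interval is `1 + 3/0.1 = 31` s (the gamma
#' beta parameter is a rate: the printed mean only works out that way) and
#' the variance is `3/0.1^2 = 300` s^2.
#'
#' @param n number of intervals.
#' @param design a [SimulationDesign-class] supplying shape/rate/offset.
#' @param seed optional RNG seed.
#' @return n positive reals, all greater than the offset.
#' @export
simulateGaps <- function(n, design = simulationDesign(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design@gapOffset + stats::rgamma(n, shape = design@gapShape,
                                   rate = design@gapRate)
}

#' The model specification matching the validation simulator
#'
#' Intercept + treatment contrasts for the movement state and the error
#' category, plus the continuous drivers: four movement coefficients, four
#' error coefficients (and two origin coordinates when estimated).
#'
#' @return A [DesignSpec-class].
#' @export
validationModelSpec <- function() {
  designSpec(
    movement = list(interceptTerm(), factorTerm("state"), linearTerm("mcov")),
    error = list(interceptTerm(), factorTerm("ecat"), linearTerm("ecov")))
}

#' Simulate a heteroscedastic validation trajectory
#'
#' True positions start at (0, 0) and evolve as planar Brownian motion with
#' per-segment variance `sigma2_i = sigma2[state_i] + slope * mcov_i`
#' (independent axes, increment variance `sigma2_i * tau_i`); observed
#' positions add independent Gaussian noise with per-location variance
#' `delta2_i = delta2[cat_i] + slope * ecov_i`. States and categories are
#' sampled iid with the design probabilities; continuous covariates are
#' uniform, drawn once per segment/location. The first observed location is
#' the true origin plus noise, so origin recovery is testable.
#'
#' @param design a [SimulationDesign-class].
#' @param n number of locations (defaults to `design@nLocations`).
#' @param seed optional RNG seed (byte-for-byte reproducibility).
#' @return A [SimulatedTrajectory-class] carrying the trajectory with its
#'   covariate tables, the generating coefficients coded exactly as
#'   [buildDesign()] codes them, and the realized variance vectors.
#' @export
simulateTrajectory <- function(design = simulationDesign(),
                               n = design@nLocations, seed = NULL) {
  validObject(design)
  if (!is.null(seed)) set.seed(seed)
  nSeg <- n - 1L
  if (nSeg < 1L) .configError("need at least 2 locations")
  taus <- simulateGaps(nSeg, design)
  times <- c(0, cumsum(taus))
  nStates <- length(design@stateProbs)
  state <- sample.int(nStates, nSeg, replace = TRUE, prob = design@stateProbs)
  mcov <- stats::runif(nSeg, design@movementCovRange[1], design@movementCovRange[2])
  sigma2 <- design@stateSigma2[state] + design@movementSlope * mcov
  nCats <- length(design@errorCatProbs)
  ecat <- sample.int(nCats, n, replace = TRUE, prob = design@errorCatProbs)
  ecov <- stats::runif(n, design@errorCovRange[1], design@errorCovRange[2])
  delta2 <- design@errorCatDelta2[ecat] + design@errorSlope * ecov
  stepSd <- sqrt(sigma2 * taus)
  true <- rbind(c(0, 0),
                cbind(cumsum(stats::rnorm(nSeg, 0, stepSd)),
                      cumsum(stats::rnorm(nSeg, 0, stepSd))))
  noiseSd <- sqrt(delta2)
  obs <- true + cbind(stats::rnorm(n, 0, noiseSd), stats::rnorm(n, 0, noiseSd))
  traj <- trajectory(
    times, obs,
    locationCovariates = data.frame(
      ecat = factor(paste0("c", ecat), levels = paste0("c", seq_len(nCats))),
      ecov = ecov),
    segmentCovariates = data.frame(
      state = factor(paste0("s", state), levels = paste0("s", seq_len(nStates))),
      mcov = mcov))
  truth <- bbcmParams(
    c(design@stateSigma2[1], design@stateSigma2[-1] - design@stateSigma2[1],
      design@movementSlope),
    c(design@errorCatDelta2[1], design@errorCatDelta2[-1] - design@errorCatDelta2[1],
      design@errorSlope),
    gamma = c(0, 0))
  spec <- validationModelSpec()
  dsn <- buildDesign(traj, spec)
  new("SimulatedTrajectory",
      trajectory = traj, truth = truth, sigma2 = sigma2, delta2 = delta2,
      modelSpec = spec, parameterNames = .paramNames(dsn, TRUE))
}

#' Simulate a trajectory with a periodic (circadian) movement pattern
#'
#' Timestamps are regularly spaced over the duration; each segment's true
#' movement variance is the segment average of the circular-spline pattern
#' `sum_j patternBeta[j] B_j(t)`, and the location error is constant
#' (default `delta2 = 10` m^2).
#'
#' @param patternBeta K positive spline coefficients (m^2/s scale).
#' @param basis the [SplineBasis-class] of the pattern.
#' @param durationDays track duration in days (default 10).
#' @param n number of locations.
#' @param delta2 constant location-error variance (m^2).
#' @param seed optional RNG seed.
#' @return A [SimulatedTrajectory-class]; its `modelSpec` is the matching
#'   spline + error-intercept model.
#' @export
simulatePeriodicTrajectory <- function(patternBeta, basis, durationDays = 10,
                                       n = 500, delta2 = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(patternBeta) != nBasis(basis))
    .configError("patternBeta length must match the number of basis functions")
  grid <- seq(0, basis@period, length.out = 2001)
  if (any(evalSpline(basis, grid) %*% patternBeta <= 0))
    .configError("pattern implies non-positive sigma^2 somewhere in the period")
  times <- seq(0, durationDays * 86400, length.out = n)
  taus <- diff(times)
  segAvg <- segmentAverageSpline(basis, times[-n], times[-1])
  sigma2 <- drop(segAvg %*% patternBeta)
  if (any(sigma2 <= 0))
    .configError("pattern implies non-positive segment-averaged sigma^2")
  stepSd <- sqrt(sigma2 * taus)
  true <- rbind(c(0, 0),
                cbind(cumsum(stats::rnorm(n - 1L, 0, stepSd)),
                      cumsum(stats::rnorm(n - 1L, 0, stepSd))))
  obs <- true + matrix(stats::rnorm(2 * n, 0, sqrt(delta2)), ncol = 2)
  traj <- trajectory(times, obs)
  spec <- designSpec(movement = list(splineTerm(basis)),
                     error = list(interceptTerm()))
  dsn <- buildDesign(traj, spec)
  new("SimulatedTrajectory",
      trajectory = traj,
      truth = bbcmParams(patternBeta, delta2, gamma = c(0, 0)),
      sigma2 = sigma2, delta2 = rep(delta2, n),
      modelSpec = spec, parameterNames = .paramNames(dsn, TRUE))
}

setMethod("show", "SimulatedTrajectory", function(object) {
  cat("Simulated trajectory with known truth\n")
  show(object@trajectory)
  cat("  truth: ")
  cat(paste(object@parameterNames,
            signif(.packParams(object@truth), 4),
            sep = " = ", collapse = ", "), "\n")
})
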