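test_that("increment covariance matches the separated-variance band formulas", {
  # n = 1: sigma2*tau + delta1^2 + delta2^2 = 1*2 + 1 + 1 = 4
  c1 <- buildIncrementCovariance(1, c(1, 1), 2)
  expect_equal(c1@diag, 4)
  expect_length(c1@offdiag, 0L)

  # n = 2 worked example
  c2 <- buildIncrementCovariance(c(1, 2), c(0.5, 0.5, 0.5), c(1, 1))
  expect_equal(c2@diag, c(2, 3))
  expect_equal(c2@offdiag, -0.5)

  # constant sigma2 = s, delta2 = d reduces to the homoscedastic matrix
  s <- 1.7; dd <- 0.4; taus <- c(2, 5, 3)
  ch <- buildIncrementCovariance(rep(s, 3), rep(dd, 4), taus)
  expect_equal(ch@diag, s * taus + 2 * dd)
  expect_equal(ch@offdiag, rep(-dd, 2))

  expect_error(buildIncrementCovariance(c(1, 1), c(1, 1), c(1, 1)),
               class = "bbcmConfigError")
  expect_error(buildIncrementCovariance(1, c(1, 0), 1),
               class = "bbcmDataError")
})

test_that("origin-extended covariance has the printed leading entries and
           stays positive definite", {
  co <- buildOriginCovariance(1, c(1, 1), 1)
  expect_equal(as.matrix(co), rbind(c(1, -1), c(-1, 3)))

  # delta1^2 -> 0 pins the origin at the first observed location
  co0 <- buildOriginCovariance(1, c(1e-12, 1), 1)
  expect_equal(as.matrix(co0)[1, ], c(1e-12, -1e-12))

  set.seed(15)
  for (rep in 1:200) {
    n <- sample(2:49, 1)
    co <- buildOriginCovariance(runif(n, 0.1, 3), runif(n + 1, 0.1, 3),
                                runif(n, 0.5, 50))
    expect_gt(min(eigen(as.matrix(co), symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("tridiagonal log-density equals the dense oracle", {
  expect_equal(
    tridiagGaussianLogpdf(0, new("TribandedCovariance", diag = 1,
                                 offdiag = numeric(0))),
    -0.5 * log(2 * pi))
  # frozen worked example: det 3, quadratic form 2
  expect_equal(
    tridiagGaussianLogpdf(c(1, 1), new("TribandedCovariance", diag = c(2, 2),
                                       offdiag = -1)),
    -3.3871832107, tolerance = 1e-9)

  set.seed(16)
  for (rep in 1:200) {
    k <- sample(1:30, 1)
    dg <- runif(k, 0.5, 4)
    od <- if (k > 1) runif(k - 1, -0.45, 0.45) else numeric(0)
    cov <- new("TribandedCovariance", diag = dg, offdiag = od)
    x <- rnorm(k)
    expect_equal(tridiagGaussianLogpdf(x, cov),
                 denseMvnLogpdf(x, as.matrix(cov)), tolerance = 1e-10)
  }

  # non-positive-definite input signals infeasibility as -Inf
  bad <- new("TribandedCovariance", diag = c(1, 1), offdiag = -2)
  expect_identical(tridiagGaussianLogpdf(c(1, 1), bad), -Inf)
})

test_that("model likelihood: two-location reduction, translation and axis
           invariance, dense oracle, infeasibility", {
  tr <- trajectory(c(0, 4), rbind(c(0, 0), c(2, -1)))
  d <- buildDesign(tr, designSpec(movement = list(interceptTerm()),
                                  error = list(interceptTerm())))
  s <- 0.8; dd <- 0.3
  ll <- bbcmLoglik(tr, d, bbcmParams(s, dd))
  v <- s * 4 + 2 * dd
  expect_equal(ll, dnorm(2, 0, sqrt(v), log = TRUE) +
                     dnorm(-1, 0, sqrt(v), log = TRUE))

  sim <- simulateTrajectory(n = 100, seed = 21)
  traj <- sim@trajectory
  dsn <- buildDesign(traj, sim@modelSpec)
  p <- sim@truth
  llRef <- bbcmLoglik(traj, dsn, p)

  # dense multivariate-normal oracle (origin-extended, both axes)
  sigma2 <- variancesFromDesign(movementMatrix(dsn), p@betaSigma)
  delta2 <- variancesFromDesign(errorMatrix(dsn), p@betaDelta)
  S <- as.matrix(buildOriginCovariance(sigma2, delta2, timeLags(traj)))
  z <- trackCoords(traj)
  X <- rbind(z[1, ] - p@gamma, diff(z))
  expect_equal(llRef, denseMvnLogpdf(X, S), tolerance = 1e-9)

  # rigid translation with matched origin changes nothing
  shifted <- trajectory(trackTimes(traj), sweep(z, 2, c(250, -90), "+"),
                        locationCovariates(traj), segmentCovariates(traj))
  dsnS <- buildDesign(shifted, sim@modelSpec)
  pShift <- bbcmParams(p@betaSigma, p@betaDelta, p@gamma + c(250, -90))
  expect_equal(bbcmLoglik(shifted, dsnS, pShift), llRef, tolerance = 1e-9)

  # swapping the x/y axes changes nothing (isotropic model, shared Sigma)
  swapped <- trajectory(trackTimes(traj), z[, c(2, 1)],
                        locationCovariates(traj), segmentCovariates(traj))
  dsnW <- buildDesign(swapped, sim@modelSpec)
  pSwap <- bbcmParams(p@betaSigma, p@betaDelta, p@gamma[c(2, 1)])
  expect_equal(bbcmLoglik(swapped, dsnW, pSwap), llRef, tolerance = 1e-9)

  # infeasible coefficients reject with -Inf rather than erroring
  bad <- bbcmParams(c(-1, 0, 0, 0), p@betaDelta, p@gamma)
  expect_identical(bbcmLoglik(traj, dsn, bad), -Inf)

  # without gamma only increments enter
  inc <- bbcmParams(p@betaSigma, p@betaDelta)
  Sinc <- as.matrix(buildIncrementCovariance(sigma2, delta2, timeLags(traj)))
  expect_equal(bbcmLoglik(traj, dsn, inc), denseMvnLogpdf(diff(z), Sinc),
               tolerance = 1e-9)
})

test_that("fixed-origin and estimated-origin fits agree on the shared
           coefficients", {
  sim <- simulateTrajectory(n = 800, seed = 22)
  dsn <- buildDesign(sim@trajectory, sim@modelSpec)
  fFix <- fitMle(sim@trajectory, dsn, estimateOrigin = FALSE)
  fEst <- fitMle(sim@trajectory, dsn, estimateOrigin = TRUE)
  # origin estimation only adds (one location's worth of) information about
  # gamma; variance estimation is driven by the distances between
  # locations, so the well-identified movement coefficients agree and the
  # estimated-origin solution is near-optimal for the increments-only
  # likelihood
  expect_equal(coefficients(fFix)[1:4], coefficients(fEst)[1:4],
               tolerance = 0.05)
  cf <- coefficients(fEst)
  llIncAtEst <- bbcmLoglik(sim@trajectory, dsn, bbcmParams(cf[1:4], cf[5:8]))
  expect_gt(llIncAtEst, logLik(fFix) - 2)
  expect_lte(llIncAtEst, logLik(fFix) + 1e-6)
  expect_equal(fEst@nParams, fFix@nParams + 2L)
})

test_that("banded likelihood evaluation scales linearly, not quadratically,
           in track length", {
  timeEval <- function(k) {
    dg <- runif(k, 1, 3)
    od <- runif(k - 1, -0.4, 0.4)
    cov <- new("TribandedCovariance", diag = dg, offdiag = od)
    x <- matrix(rnorm(2 * k), ncol = 2)
    # median over repeats to tame timer noise
    median(vapply(1:5, function(i)
      system.time(tridiagGaussianLogpdf(x, cov))[["elapsed"]], numeric(1)))
  }
  set.seed(91)
  t3 <- timeEval(1e3); t5 <- timeEval(1e5)
  # 100x the size must cost far less than the 10000x of a dense/quadratic
  # method; allow a wide margin for timer granularity
  expect_lt(t5, max(t3, 0.001) * 500)
})
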