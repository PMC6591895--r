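segTrack <- function(n, segdf = NULL, locdf = NULL) {
  trajectory(seq(0, n * 10, by = 10), matrix(rnorm(2 * (n + 1)), ncol = 2),
             locationCovariates = locdf, segmentCovariates = segdf)
}

test_that("design matrices: intercept, linear pass-through, treatment coding", {
  tr <- segTrack(3, segdf = data.frame(c = c(0.1, 0.2, 0.3)))
  d <- buildDesign(tr, designSpec(
    movement = list(interceptTerm(), linearTerm("c")),
    error = list(interceptTerm())))
  expect_equal(movementMatrix(d),
               cbind("(intercept)" = rep(1, 3), c = c(0.1, 0.2, 0.3)))

  tr <- segTrack(6, segdf = data.frame(
    f = factor(c("a", "b", "c", "a", "c", "b"))))
  d <- buildDesign(tr, designSpec(
    movement = list(interceptTerm(), factorTerm("f")),
    error = list(interceptTerm())))
  # 3 levels -> intercept + 2 contrasts, NOT 4 columns
  expect_equal(ncol(movementMatrix(d)), 3L)
  expect_equal(colnames(movementMatrix(d)), c("(intercept)", "f.b", "f.c"))
  expect_equal(movementMatrix(d)[, "f.b"], c(0, 1, 0, 0, 0, 1))

  # character covariates: baseline is the first-observed level
  tr2 <- segTrack(3, segdf = data.frame(g = c("z", "a", "z"),
                                        stringsAsFactors = FALSE))
  d2 <- buildDesign(tr2, designSpec(
    movement = list(interceptTerm(), factorTerm("g")),
    error = list(interceptTerm())))
  expect_equal(colnames(movementMatrix(d2))[2], "g.a")

  expect_error(buildDesign(tr, designSpec(
    movement = list(interceptTerm(), linearTerm("nope")),
    error = list(interceptTerm()))), class = "bbcmConfigError")
  tr3 <- segTrack(3, segdf = data.frame(f = factor(rep("a", 3))))
  expect_error(buildDesign(tr3, designSpec(
    movement = list(interceptTerm(), factorTerm("f")),
    error = list(interceptTerm()))), "single level")
})

test_that("validation design has four movement and four error columns", {
  sim <- simulateTrajectory(n = 50, seed = 2)
  d <- buildDesign(sim@trajectory, sim@modelSpec)
  expect_equal(ncol(movementMatrix(d)), 4L)
  expect_equal(ncol(errorMatrix(d)), 4L)
  # ... so that with the origin the full model has 10 parameters
  expect_length(bbcm:::.paramNames(d, TRUE), 10L)
})

test_that("a full circular spline plus free intercept is rejected", {
  b <- uniformSplineBasis(5)
  expect_error(designSpec(
    movement = list(interceptTerm(), splineTerm(b)),
    error = list(interceptTerm())), "multiple solutions")
  # the separated-constants option makes the combination identifiable
  spec <- designSpec(
    movement = list(interceptTerm(), splineTerm(b, separateConstant = TRUE)),
    error = list(interceptTerm()))
  sim <- simulatePeriodicTrajectory(rep(1, 5), b, durationDays = 2, n = 30,
                                    seed = 3)
  d <- buildDesign(sim@trajectory, spec)
  expect_equal(ncol(movementMatrix(d)), 1L + 4L)
})

test_that("spline columns are segment averages on the movement side and
           instantaneous values on the error side", {
  b <- uniformSplineBasis(6)
  sim <- simulatePeriodicTrajectory(rep(2, 6), b, durationDays = 2, n = 40,
                                    seed = 4)
  tr <- sim@trajectory
  d <- buildDesign(tr, designSpec(movement = list(splineTerm(b)),
                                  error = list(splineTerm(b))))
  tt <- trackTimes(tr, absolute = TRUE)
  expect_equal(movementMatrix(d),
               segmentAverageSpline(b, tt[-length(tt)], tt[-1]),
               ignore_attr = TRUE)
  expect_equal(errorMatrix(d), evalSpline(b, tt), ignore_attr = TRUE)
})

test_that("scaling centres/scales only continuous columns and is exactly
           invertible on coefficients", {
  tr <- segTrack(3, segdf = data.frame(c = c(0, 0.25, 0.5)))
  d <- buildDesign(tr, designSpec(
    movement = list(interceptTerm(), linearTerm("c")),
    error = list(interceptTerm())))
  s <- scaleColumns(d)
  expect_equal(mean(movementMatrix(s)[, "c"]), 0)
  expect_equal(sd(movementMatrix(s)[, "c"]), 1)
  expect_equal(movementMatrix(s)[, "(intercept)"], rep(1, 3),
               ignore_attr = TRUE)

  # round trip beta_scaled -> original: variances identical
  beta <- c(1.5, 0.7)
  rec <- s@scaling$movement
  betaScaled <- c(beta[1] + beta[2] * rec$center[2], beta[2] * rec$scale[2])
  expect_equal(backTransformBeta(s, betaScaled, "movement"), beta)
  expect_equal(drop(movementMatrix(s) %*% betaScaled),
               drop(movementMatrix(d) %*% beta))

  zv <- segTrack(3, segdf = data.frame(c = rep(2, 3)))
  dz <- buildDesign(zv, designSpec(
    movement = list(interceptTerm(), linearTerm("c")),
    error = list(interceptTerm())))
  expect_warning(scaleColumns(dz), "zero variance")
})

test_that("fitting on scaled and unscaled designs gives the same estimates", {
  sim <- simulateTrajectory(n = 200, seed = 31)
  d <- buildDesign(sim@trajectory, sim@modelSpec)
  f1 <- fitMle(sim@trajectory, d, scale = TRUE)
  f2 <- fitMle(sim@trajectory, d, scale = FALSE)
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-5)
  expect_equal(coefficients(f1), coefficients(f2), tolerance = 0.02)
})

test_that("variances from a design are row-wise products, infeasibility is
           a signal carrying the offending row", {
  expect_equal(variancesFromDesign(cbind(1, 0.25), c(0.3, 2)), 0.8)
  expect_equal(variancesFromDesign(matrix(1, 5, 1), 5), rep(5, 5))
  err <- tryCatch(variancesFromDesign(matrix(1, 3, 2), c(0, 0)),
                  error = identity)
  expect_s3_class(err, "bbcmInfeasibleError")
  expect_equal(err$row, 1L)
  err2 <- tryCatch(
    variancesFromDesign(cbind(1, c(0, 0, -2)), c(1, 1)), error = identity)
  expect_equal(err2$row, 3L)
})

test_that("intercept feasibility bound is tight and matches a row scan", {
  M <- cbind(1, c(-1, 0, 1))
  b <- interceptFeasibleBound(M, 0.4)
  expect_equal(as.numeric(b), 0.4)
  expect_equal(attr(b, "direction"), "greater")
  expect_equal(as.numeric(interceptFeasibleBound(M, 0)), 0)

  set.seed(12)
  for (rep in 1:5) {
    M <- cbind(runif(50, 0.5, 2), matrix(rnorm(100), ncol = 2))
    beta2 <- rnorm(2)
    b <- interceptFeasibleBound(M, beta2)
    # brute-force row scan: smallest beta1 keeping every row positive
    oracle <- max(-(M[, -1] %*% beta2) / M[, 1])
    expect_equal(as.numeric(b), oracle)
    eps <- 1e-9 + abs(oracle) * 1e-9
    expect_true(all(M %*% c(oracle + 1e-6 + eps, beta2) > 0))
    expect_false(all(M %*% c(oracle - 1e-6 - eps, beta2) > 0))
  }

  expect_error(interceptFeasibleBound(cbind(c(1, -1), 0:1), 0.2),
               class = "bbcmConfigError")
})

test_that("hot-day window duplication copies exactly the basis functions
           peaking in the window", {
  b <- uniformSplineBasis(10)
  sim <- simulatePeriodicTrajectory(rep(2, 10), b, durationDays = 4, n = 200,
                                    seed = 6)
  d <- buildDesign(sim@trajectory,
                   designSpec(movement = list(splineTerm(b)),
                              error = list(interceptTerm())))
  win <- c(9, 12) * 3600
  ind <- rep(c(0, 1), length.out = 200 - 1)

  # oracle: argmax of each basis function on a 1-second grid
  grid <- seq(0, 86400 - 1, by = 1)
  peaks <- grid[apply(evalSpline(b, grid), 2, which.max)]
  expectDup <- which(peaks >= win[1] & peaks < win[2])
  d2 <- duplicateSplineColumns(d, ind, win)
  expect_equal(ncol(movementMatrix(d2)),
               ncol(movementMatrix(d)) + length(expectDup))
  dupNames <- grep("\\.dup$", colnames(movementMatrix(d2)), value = TRUE)
  expect_setequal(sub("\\.dup$", "", dupNames),
                  colnames(movementMatrix(d))[expectDup])

  # all-false indicator: originals unchanged, appended columns all zero
  d0 <- duplicateSplineColumns(d, rep(0, 199), win)
  M0 <- movementMatrix(d0)
  expect_equal(M0[, seq_len(ncol(movementMatrix(d)))], movementMatrix(d))
  expect_true(all(M0[, grep("\\.dup$", colnames(M0))] == 0))

  # all-true indicator at matched coefficients: identical likelihood
  d1 <- duplicateSplineColumns(d, rep(1, 199), win)
  beta <- runif(10, 0.5, 2)
  betaDup <- c(beta, beta[expectDup])
  betaDup[expectDup] <- 0              # originals are zeroed by the indicator
  ll1 <- bbcmLoglik(sim@trajectory, d1,
                    bbcmParams(betaDup, 10, gamma = c(0, 0)))
  ll0 <- bbcmLoglik(sim@trajectory, d,
                    bbcmParams(beta, 10, gamma = c(0, 0)))
  expect_equal(ll1, ll0, tolerance = 1e-10)

  expect_error(duplicateSplineColumns(d, ind, c(1000, 1001)),
               class = "bbcmConfigError")  # no peak in a 1-second window
})
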