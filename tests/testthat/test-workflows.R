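test_that("knot scan tabulates one AIC row per requested basis size", {
  b <- uniformSplineBasis(6)
  pat <- c(0.5, 0.6, 2.5, 4, 2, 0.8)
  sim <- simulatePeriodicTrajectory(pat, b, durationDays = 4, n = 400,
                                    delta2 = 5, seed = 81)
  tab <- knotScan(sim@trajectory, c(4, 6), control = list(maxit = 2000))
  expect_equal(tab$knots, c(4, 6))
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$aic)))
  expect_equal(min(tab$dAic), 0)
  expect_equal(tab$k, c(4, 6) + 3L)   # basis + error intercept + origin
  expect_equal(tab$aic, 2 * tab$k - 2 * tab$logLik)
  # a failed fit keeps its row and the scan continues
  tab2 <- knotScan(sim@trajectory, c(3, 6), control = list(maxit = 1000))
  expect_true(is.na(tab2$aic[1]) && !is.na(tab2$error[1]))
  expect_true(is.finite(tab2$aic[2]))
})

test_that("simulate workflow archives config and is reproducible from
           config + seed", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- list(action = "simulate", seed = 5,
              simulate = list(n = 60))
  runBbcm(cfg, outputDir = out1)
  runBbcm(cfg, outputDir = out2)
  expect_true(file.exists(file.path(out1, "track.csv")))
  expect_true(file.exists(file.path(out1, "truth.json")))
  expect_true(file.exists(file.path(out1, "config.yaml")))
  expect_identical(readLines(file.path(out1, "track.csv")),
                   readLines(file.path(out2, "track.csv")))
  truth <- jsonlite::read_json(file.path(out1, "truth.json"))
  expect_length(truth, 10L)
  expect_equal(truth[["sigma2.mcov"]], 2)
})

test_that("fit workflow: end-to-end read -> design -> fit -> report with 10
           parameters on the validation fixture", {
  simDir <- withr::local_tempdir()
  runBbcm(list(action = "simulate", seed = 6, simulate = list(n = 250)),
          outputDir = simDir)
  fitDir <- withr::local_tempdir()
  cfg <- list(
    action = "fit", seed = 7,
    trajectory = file.path(simDir, "track.csv"),
    segment_columns = c("state", "mcov"),
    model = list(
      movement = list(list(type = "intercept"), list(type = "factor", name = "state"),
                      list(type = "linear", name = "mcov")),
      error = list(list(type = "intercept"), list(type = "factor", name = "ecat"),
                   list(type = "linear", name = "ecov"))),
    inference = list(mode = "mcmc", chains = 2, iterations = 400,
                     warmup = 200, thin = 4))
  # tiny chains: the R-hat > 1.1 poor-fit warning is expected here
  res <- suppressWarnings(runBbcm(cfg, outputDir = fitDir))
  fj <- jsonlite::read_json(file.path(fitDir, "fit.json"))
  expect_length(fj$parameters, 10L)
  expect_true(file.exists(file.path(fitDir, "draws.csv")))
  expect_true(file.exists(file.path(fitDir, "intervals.csv")))
  expect_true(is.numeric(fj$maxRhat))

  # same config + seed twice -> identical outputs
  fitDir2 <- withr::local_tempdir()
  suppressWarnings(runBbcm(cfg, outputDir = fitDir2))
  expect_identical(readLines(file.path(fitDir, "draws.csv")),
                   readLines(file.path(fitDir2, "draws.csv")))
})

test_that("ud workflow writes normalized grids and contour masks", {
  simDir <- withr::local_tempdir()
  runBbcm(list(action = "simulate", seed = 8, simulate = list(n = 40)),
          outputDir = simDir)
  udDir <- withr::local_tempdir()
  cfg <- list(
    action = "ud",
    trajectory = file.path(simDir, "track.csv"),
    segment_columns = c("state", "mcov"),
    model = list(
      movement = list(list(type = "intercept"), list(type = "factor", name = "state"),
                      list(type = "linear", name = "mcov")),
      error = list(list(type = "intercept"), list(type = "factor", name = "ecat"),
                   list(type = "linear", name = "ecov"))),
    ud = list(cell_size = 4))
  runBbcm(cfg, outputDir = udDir)
  ud <- read.csv(file.path(udDir, "ud.csv"))
  expect_equal(sum(ud$mass), 1, tolerance = 1e-9)
  c50 <- read.csv(file.path(udDir, "contour_50.csv"))
  c95 <- read.csv(file.path(udDir, "contour_95.csv"))
  expect_gt(nrow(c95), nrow(c50))
})

test_that("unknown actions and malformed configs raise configuration errors", {
  expect_error(runBbcm(list(action = "nope"), outputDir = withr::local_tempdir()),
               class = "bbcmConfigError")
  expect_error(runBbcm(list(action = "fit"), outputDir = withr::local_tempdir()),
               class = "bbcmConfigError")
  expect_error(runBbcm(42), class = "bbcmConfigError")
})

test_that("hot-day duplication recovers distinct morning activity levels
           from a two-regime simulation", {
  b <- uniformSplineBasis(6)           # peaks every 4 h from 02:00
  period <- 86400
  n <- 3000
  times <- seq(0, 10 * 86400, length.out = n)
  hotDay <- (floor(times / 86400) %% 2) == 1   # alternate cool/hot days
  segHot <- hotDay[-n]
  win <- c(7, 13) * 3600               # spans the 08:00 and 12:00 peaks
  grid <- seq(0, period - 60, by = 60)
  peaks <- grid[apply(evalSpline(b, grid), 2, which.max)]
  winIdx <- which(peaks >= win[1] & peaks < win[2])
  coolBeta <- rep(0.8, 6)
  coolBeta[winIdx] <- 4                # busy mornings on cool days
  hotBeta <- coolBeta
  hotBeta[winIdx] <- 1                 # suppressed morning movement when hot
  segAvg <- segmentAverageSpline(b, times[-n], times[-1])
  sigma2 <- ifelse(segHot, drop(segAvg %*% hotBeta), drop(segAvg %*% coolBeta))
  set.seed(82)
  taus <- diff(times)
  true <- rbind(c(0, 0), cbind(cumsum(rnorm(n - 1, 0, sqrt(sigma2 * taus))),
                               cumsum(rnorm(n - 1, 0, sqrt(sigma2 * taus)))))
  obs <- true + matrix(rnorm(2 * n, 0, sqrt(6)), ncol = 2)
  traj <- trajectory(times, obs,
                     segmentCovariates = data.frame(hot = as.numeric(segHot)))
  design <- buildDesign(traj, designSpec(movement = list(splineTerm(b)),
                                         error = list(interceptTerm())))
  design <- duplicateSplineColumns(design, segHot, win)
  fit <- fitMle(traj, design)
  cf <- coefficients(fit)
  est <- cf[seq_len(ncol(movementMatrix(design)))]
  nDup <- length(winIdx)
  dupEst <- est[6 + seq_len(nDup)]     # hot-day window coefficients
  coolEst <- est[winIdx]               # cool-day window coefficients
  expect_equal(unname(dupEst), rep(1, nDup), tolerance = 0.5)
  expect_equal(unname(coolEst), coolBeta[winIdx], tolerance = 0.35)
  expect_true(all(coolEst - dupEst > 1))
})
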