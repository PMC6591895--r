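## cli_interface backing functions: config-driven runs and the knot-scan /
## AIC workflow. The shell entry point (inst/scripts/bbcm.R) is a thin
## wrapper over these.

#' AIC scan over the number of spline knots
#'
#' Fits one maximum-likelihood model per knot count, each with a uniform
#' circular basis as the only movement term, and tabulates AIC. This is the
#' standard way to choose the smoothness of the daily activity pattern:
#' AIC drops while added knots capture real structure and rises once they
#' fit noise.
#'
#' @param traj a [Trajectory-class].
#' @param knotCounts integer vector of basis sizes to try (each >= 4).
#' @param period spline period, seconds.
#' @param errorTerms term list for the error side (default single
#'   intercept).
#' @param estimateOrigin,scale,control passed to [fitMle()].
#' @return data.frame `knots`, `logLik`, `k`, `aic`, `dAic` (relative to
#'   the best successful fit), one row per requested knot count, in the
#'   order requested. Failed fits keep their row with `NA` values and an
#'   `error` message; the scan continues.
#' @export
knotScan <- function(traj, knotCounts, period = 86400,
                     errorTerms = list(interceptTerm()),
                     estimateOrigin = TRUE, scale = TRUE, control = list()) {
  rows <- lapply(knotCounts, function(K) {
    fit <- tryCatch({
      spec <- designSpec(
        movement = list(splineTerm(uniformSplineBasis(K, period))),
        error = errorTerms)
      fitMle(traj, buildDesign(traj, spec), estimateOrigin = estimateOrigin,
             scale = scale, control = control,
             modelLabel = sprintf("spline-%dknots", K))
    }, error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(knots = K, logLik = NA_real_, k = NA_integer_,
                 aic = NA_real_, error = conditionMessage(fit))
    else
      data.frame(knots = K, logLik = fit@logLik, k = fit@nParams,
                 aic = fit@aic, error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  best <- suppressWarnings(min(tab$aic, na.rm = TRUE))
  tab$dAic <- tab$aic - best
  tab[c("knots", "logLik", "k", "aic", "dAic", "error")]
}

.termFromConfig <- function(t) {
  switch(t$type,
    intercept = interceptTerm(),
    linear = linearTerm(t$name, scale = !isFALSE(t$scale)),
    factor = factorTerm(t$name),
    spline = {
      period <- if (is.null(t$period)) 86400 else t$period
      basis <- if (is.null(t$knots)) .configError("spline term needs 'knots'")
        else if (length(t$knots) == 1L) uniformSplineBasis(t$knots, period)
        else splineBasis(t$knots, period)
      splineTerm(basis, separateConstant = isTRUE(t$separate_constant))
    },
    .configError(sprintf("unknown term type '%s' in config", t$type)))
}

.specFromConfig <- function(model) {
  if (is.null(model$movement) || is.null(model$error))
    .configError("config model needs 'movement' and 'error' term lists")
  designSpec(movement = lapply(model$movement, .termFromConfig),
             error = lapply(model$error, .termFromConfig))
}

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .configError("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .configError("config must be a list or a YAML path")
  config
}

.readConfigTrajectory <- function(config) {
  if (is.null(config$trajectory)) .configError("config needs a 'trajectory' path")
  cm <- config$column_map
  if (is.null(cm)) cm <- list(timestamp = "timestamp", x = "x", y = "y")
  readTrajectory(config$trajectory, columnMap = cm,
                 segmentCols = as.character(unlist(config$segment_columns)))
}

#' Run a configured BBCM workflow
#'
#' Executes one of the workflow actions — `simulate`, `fit`, `knot-scan` or
#' `ud` — from a configuration list or YAML file, writing results (and an
#' archived copy of the configuration, for reproducibility from config +
#' seed) into the output directory.
#'
#' Config keys: `action`; `output_dir`; `seed`; `trajectory`/`column_map`/
#' `segment_columns` for file input; `model` with `movement`/`error` term
#' lists (`type: intercept|linear|factor|spline`, spline fields `knots`
#' (count or positions) and `period`); `inference` with `mode: mle|mcmc`
#' and `chains`, `iterations`, `warmup`, `thin`, `estimate_origin`;
#' `simulate` with `n` and optional [simulationDesign()] overrides;
#' `knots` (vector) for the scan; `ud` with `cell_size`, `margin`.
#'
#' @param config list or YAML file path.
#' @param outputDir overrides `config$output_dir`.
#' @return invisibly, a list of result objects (also written to files).
#' @export
runBbcm <- function(config, outputDir = NULL) {
  config <- .readConfig(config)
  out <- if (!is.null(outputDir)) outputDir else config$output_dir
  if (is.null(out)) .configError("an output directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(config, file.path(out, "config.yaml"))
  action <- if (is.null(config$action)) "fit" else config$action
  seed <- config$seed
  switch(action,
    simulate = {
      simArgs <- config$simulate
      ## YAML 1.1 reads a bare `n:` key as a boolean, so the config key is
      ## n_locations; plain-list configs may still say n
      n <- if (!is.null(simArgs$n_locations)) simArgs$n_locations
        else if (!is.null(simArgs$n)) simArgs$n else 1000L
      simArgs$n <- NULL; simArgs$n_locations <- NULL
      simArgs <- simArgs[names(simArgs) %in% names(formals(simulationDesign))]
      dsn <- do.call(simulationDesign, simArgs)
      sim <- simulateTrajectory(dsn, n = n, seed = seed)
      writeTrajectory(sim@trajectory, file.path(out, "track.csv"))
      jsonlite::write_json(
        as.list(setNames(.packParams(sim@truth), sim@parameterNames)),
        file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
      invisible(list(simulation = sim))
    },
    fit = {
      traj <- .readConfigTrajectory(config)
      spec <- .specFromConfig(config$model)
      design <- buildDesign(traj, spec)
      inf <- config$inference
      estOrigin <- !isFALSE(inf$estimate_origin)
      mode <- if (is.null(inf$mode)) "mle" else inf$mode
      fit <- fitMle(traj, design, estimateOrigin = estOrigin)
      maxRhat <- NULL
      chains <- NULL
      if (identical(mode, "mcmc")) {
        chains <- fitMcmc(
          traj, design,
          chains = if (is.null(inf$chains)) 4 else inf$chains,
          iterations = if (is.null(inf$iterations)) 5000 else inf$iterations,
          warmup = if (is.null(inf$warmup)) 2500 else inf$warmup,
          thin = if (is.null(inf$thin)) 10 else inf$thin,
          seed = seed, estimateOrigin = estOrigin)
        rhat <- splitRhat(chains)
        maxRhat <- max(rhat, na.rm = TRUE)
        message(sprintf("max split R-hat: %.4f", maxRhat))
        if (maxRhat > 1.1)
          warning("split R-hat above 1.1 indicates a poor model fit")
        writeChainsCsv(chains, file.path(out, "draws.csv"))
        utils::write.csv(posteriorIntervals(chains),
                         file.path(out, "intervals.csv"), row.names = FALSE)
      }
      writeFitJson(fit, file.path(out, "fit.json"), maxRhat = maxRhat)
      invisible(list(fit = fit, chains = chains))
    },
    `knot-scan` = {
      traj <- .readConfigTrajectory(config)
      knots <- unlist(config$knots)
      if (is.null(knots)) .configError("knot-scan needs a 'knots' vector")
      errTerms <- if (is.null(config$model$error)) list(interceptTerm())
        else lapply(config$model$error, .termFromConfig)
      tab <- knotScan(traj, knots, errorTerms = errTerms)
      utils::write.csv(tab, file.path(out, "knot_scan.csv"), row.names = FALSE)
      invisible(list(table = tab))
    },
    ud = {
      traj <- .readConfigTrajectory(config)
      spec <- .specFromConfig(config$model)
      design <- buildDesign(traj, spec)
      fit <- fitMle(traj, design,
                    estimateOrigin = !isFALSE(config$inference$estimate_origin))
      sigma2 <- variancesFromDesign(movementMatrix(design), fit@params@betaSigma)
      delta2 <- variancesFromDesign(errorMatrix(design), fit@params@betaDelta)
      udArgs <- config$ud
      ud <- computeUd(traj, sigma2, delta2,
                      cellSize = udArgs$cell_size, margin = udArgs$margin)
      writeUdCsv(ud, file.path(out, "ud.csv"))
      writeUdAsciiGrid(ud, file.path(out, "ud.asc"))
      for (p in c(0.5, 0.95)) {
        ct <- contourThreshold(ud, p)
        utils::write.csv(
          data.frame(x = rep(ud@x, length(ud@y))[as.vector(ct$mask)],
                     y = rep(ud@y, each = length(ud@x))[as.vector(ct$mask)]),
          file.path(out, sprintf("contour_%02d.csv", round(100 * p))),
          row.names = FALSE)
      }
      invisible(list(fit = fit, ud = ud))
    },
    .configError(sprintf("unknown action '%s'", action)))
}
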