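## inference_engine (part 1): maximum likelihood fitting.

.paramNames <- function(design, estimateOrigin) {
  c(paste0("sigma2.", colnames(design@movementMatrix)),
    paste0("delta2.", colnames(design@errorMatrix)),
    if (estimateOrigin) c("gamma.x", "gamma.y"))
}

.packParams <- function(params) {
  c(params@betaSigma, params@betaDelta, params@gamma)
}

.unpackParams <- function(theta, mSigma, mDelta, estimateOrigin) {
  bbcmParams(theta[seq_len(mSigma)],
             theta[mSigma + seq_len(mDelta)],
             if (estimateOrigin) theta[mSigma + mDelta + 1:2] else numeric(0))
}

## Closure evaluating the log-likelihood from a packed parameter vector,
## with everything that does not depend on theta precomputed.
.makeLoglik <- function(traj, design, estimateOrigin) {
  Ms <- design@movementMatrix
  Me <- design@errorMatrix
  mS <- ncol(Ms); mE <- ncol(Me)
  n <- nrow(Ms)
  taus <- timeLags(traj)
  deltas <- diff(traj@coords)
  z0 <- traj@coords[1L, ]
  innerIdx <- seq.int(2L, length.out = n - 1L)
  function(theta) {
    sigma2 <- drop(Ms %*% theta[seq_len(mS)])
    delta2 <- drop(Me %*% theta[mS + seq_len(mE)])
    if (anyNA(sigma2) || any(sigma2 <= 0) || any(delta2 <= 0)) return(-Inf)
    dgInc <- sigma2 * taus + delta2[-(n + 1L)] + delta2[-1L]
    odInner <- -delta2[innerIdx]
    if (estimateOrigin) {
      gamma <- theta[mS + mE + 1:2]
      .tridiagLogpdfC(c(delta2[1L], dgInc), c(-delta2[1L], odInner),
                      rbind(z0 - gamma, deltas))
    } else {
      .tridiagLogpdfC(dgInc, odInner, deltas)
    }
  }
}

## Moment-based feasible starting point on the (possibly scaled) design.
## The three flavors split the observed increment variance differently
## between movement and error; the likelihood of short tracks can have
## separate basins (e.g. a delta^2 -> 0 boundary optimum), so the
## optimizer is run from each and the best kept.
.defaultInit <- function(traj, design, estimateOrigin,
                         flavor = c("balanced", "error", "movement")) {
  flavor <- match.arg(flavor)
  deltas <- diff(traj@coords)
  taus <- timeLags(traj)
  total <- mean(deltas^2)                   # ~ sigma2*tau + 2*delta2 per axis
  split <- switch(flavor, balanced = 0.25, error = 0.45, movement = 0.01)
  d0 <- max(split * total, 1e-3)
  s0 <- max((total - 2 * d0) / mean(taus), total / (100 * mean(taus)), 1e-6)
  initSide <- function(mat, types, level) {
    m <- ncol(mat)
    beta <- numeric(m)
    if (any(types == "intercept")) {
      beta[which(types == "intercept")[1]] <- level
    } else if (all(types == "spline")) {
      beta[] <- level
    } else {
      ## no intercept (e.g. HDOP-only error model): least-squares towards a
      ## constant positive variance
      beta <- qr.solve(qr(mat), rep(level, nrow(mat)))
    }
    v <- drop(mat %*% beta)
    if (any(v <= 0)) {
      x1 <- mat[, 1]
      if (m > 1L && (all(x1 > 0) || all(x1 < 0))) {
        b <- interceptFeasibleBound(mat, beta[-1])
        beta[1] <- if (attr(b, "direction") == "greater")
          b + 0.1 * abs(b) + 0.01 else b - 0.1 * abs(b) - 0.01
      } else {
        beta <- beta * 0 + level        # flat fallback
      }
      v <- drop(mat %*% beta)
      if (any(v <= 0))
        .configError("could not construct a feasible starting point; supply init")
    }
    beta
  }
  bS <- initSide(design@movementMatrix, design@movementTypes, s0)
  bD <- initSide(design@errorMatrix, design@errorTypes, d0)
  bbcmParams(bS, bD, if (estimateOrigin) traj@coords[1L, ] else numeric(0))
}

## Shared MLE core: optimizes on the scaled design, returns scaled-space
## results plus what MCMC needs (objective closure, Hessian, designs).
.fitMleCore <- function(traj, design, estimateOrigin = TRUE, scale = TRUE,
                        init = NULL, control = list()) {
  scaledDesign <- if (scale) scaleColumns(design) else design
  ll <- .makeLoglik(traj, scaledDesign, estimateOrigin)
  mS <- ncol(scaledDesign@movementMatrix)
  mE <- ncol(scaledDesign@errorMatrix)
  ## always try the three moment-based starts; a user/warm start (e.g. a
  ## nested model's solution) is an additional candidate basin
  inits <- lapply(c("balanced", "error", "movement"), function(f)
    .defaultInit(traj, scaledDesign, estimateOrigin, flavor = f))
  if (!is.null(init))
    inits <- c(if (is(init, "BbcmParams")) list(init) else init, inits)
  negll <- function(theta) {
    v <- ll(theta)
    if (!is.finite(v)) 1e12 else -v
  }
  maxit <- if (is.null(control$maxit)) 5000L else control$maxit
  reltol <- if (is.null(control$reltol)) 1e-10 else control$reltol
  ## Nelder-Mead walks robustly into the feasible basin (it tolerates the
  ## -Inf cliffs), then BFGS with numerical gradients polishes; repeated
  ## while the polish still improves materially (NM simplices collapse in
  ## higher dimensions, e.g. spline models). Run from every start, keep the
  ## best.
  opt <- NULL
  for (ini in inits) {
    cur <- stats::optim(.packParams(ini), negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    for (round in 1:3) {
      polish <- tryCatch(
        stats::optim(cur$par, negll, method = "BFGS",
                     control = list(maxit = 300L, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(polish) && polish$value <= cur$value) cur <- polish
      restart <- stats::optim(cur$par, negll, method = "Nelder-Mead",
                              control = list(maxit = maxit, reltol = reltol))
      if (restart$value <= cur$value) {
        improved <- cur$value - restart$value > 0.01
        cur <- restart
        if (!improved) break
      } else break
    }
    if (is.null(opt) || cur$value < opt$value) opt <- cur
  }
  list(par = opt$par, logLik = -opt$value, convergence = opt$convergence,
       scaledDesign = scaledDesign, loglik = ll,
       mSigma = mS, mDelta = mE, estimateOrigin = estimateOrigin)
}

.fingerprint <- function(traj) {
  c(nLocations(traj), sum(traj@times), sum(traj@coords))
}

## Back-transform a packed scaled-space vector to the original scale.
.backTransformTheta <- function(core, theta) {
  d <- core$scaledDesign
  bS <- backTransformBeta(d, theta[seq_len(core$mSigma)], "movement")
  bD <- backTransformBeta(d, theta[core$mSigma + seq_len(core$mDelta)], "error")
  c(bS, bD, if (core$estimateOrigin) theta[core$mSigma + core$mDelta + 1:2])
}

#' Fit the BBCM by maximum likelihood
#'
#' Maximizes the exact increment log-likelihood over the variance
#' coefficients and (by default) the trajectory origin, by Nelder-Mead with
#' one restart. Continuous covariate columns are centred/scaled internally
#' for conditioning; reported coefficients are always on the original
#' covariate scale. Infeasible parameter vectors (non-positive generated
#' variances) have log-likelihood `-Inf` and are thereby rejected.
#'
#' @param traj a [Trajectory-class].
#' @param design an (unscaled) [VarianceDesign-class] for `traj`.
#' @param init optional [BbcmParams-class] starting point on the original
#'   scale (it is re-expressed internally when `scale = TRUE` is active);
#'   by default a moment-based feasible start is constructed, with the
#'   origin initialized at the first observed location.
#' @param estimateOrigin estimate the origin gamma (default TRUE; the
#'   assumption of a known start location is rarely justified). When FALSE
#'   only increments enter the likelihood (fixed-origin formulation).
#' @param scale scale continuous covariate columns internally.
#' @param control list: `maxit`, `reltol` for [stats::optim()].
#' @param modelLabel label used by [compareAic()].
#' @return A [FitResult-class]. Non-convergence is flagged in the
#'   `convergence` slot (0 means converged), not raised as an error.
#' @export
fitMle <- function(traj, design, init = NULL, estimateOrigin = TRUE,
                   scale = TRUE, control = list(), modelLabel = "bbcm") {
  scaledInit <- NULL
  if (!is.null(init)) {
    ## express the user's original-scale start in the scaled space
    sdsn <- if (scale) scaleColumns(design) else design
    scaledInit <- init
    if (scale) {
      recM <- sdsn@scaling$movement; recE <- sdsn@scaling$error
      bS <- init@betaSigma * recM$scale
      iM <- which(sdsn@movementTypes == "intercept")
      if (length(iM)) bS[iM[1]] <- bS[iM[1]] + sum(init@betaSigma * recM$center)
      bD <- init@betaDelta * recE$scale
      iE <- which(sdsn@errorTypes == "intercept")
      if (length(iE)) bD[iE[1]] <- bD[iE[1]] + sum(init@betaDelta * recE$center)
      scaledInit <- bbcmParams(bS, bD, init@gamma)
    }
  }
  core <- .fitMleCore(traj, design, estimateOrigin, scale, scaledInit, control)
  thetaOrig <- .backTransformTheta(core, core$par)
  params <- .unpackParams(thetaOrig, core$mSigma, core$mDelta, estimateOrigin)
  k <- core$mSigma + core$mDelta + if (estimateOrigin) 2L else 0L
  new("FitResult",
      params = params,
      parameterNames = .paramNames(design, estimateOrigin),
      logLik = core$logLik,
      aic = 2 * k - 2 * core$logLik,
      nParams = as.integer(k),
      convergence = as.integer(core$convergence),
      scaled = isTRUE(scale),
      fingerprint = .fingerprint(traj),
      modelLabel = modelLabel)
}

#' @describeIn fitMle packed named coefficient vector (original scale)
#' @param object a FitResult
#' @param ... ignored
#' @export
setMethod("coefficients", "FitResult", function(object, ...)
  setNames(.packParams(object@params), object@parameterNames))

#' @describeIn fitMle maximized log-likelihood
#' @export
setMethod("logLik", "FitResult", function(object, ...) object@logLik)

#' @describeIn fitMle Akaike information criterion, 2k - 2 logLik
#' @export
setMethod("aic", "FitResult", function(object) object@aic)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("BBCM maximum-likelihood fit ('%s')\n", object@modelLabel))
  cat(sprintf("  logLik %.3f, k = %d, AIC %.3f%s\n", object@logLik,
              object@nParams, object@aic,
              if (object@convergence != 0L) "  [optimizer did not converge]" else ""))
  print(signif(coefficients(object), 5))
})
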