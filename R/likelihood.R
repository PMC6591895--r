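## bbcm_likelihood: tridiagonal increment covariances and the exact
## Gaussian log-likelihood, O(n) via LDL' on the bands. The covariance of
## the increments is tridiagonal because consecutive increments share the
## measurement error of their common location: the error of location i+1
## enters increment i with sign + and increment i+1 with sign -, giving
## off-diagonal entries -delta_{i+1}^2.

#' Increment covariance matrix of an error-contaminated Brownian track
#'
#' Builds the symmetric tridiagonal covariance of the n coordinate
#' increments: diagonal entries `sigma2[i] * taus[i] + delta2[i] +
#' delta2[i+1]`, off-diagonal entries `-delta2[i+1]`. With constant
#' sigma^2 = s and delta^2 = d this reduces to the homoscedastic matrix
#' with diagonal `s * tau_i + 2 d`.
#'
#' @param sigma2 n positive per-segment movement variances (m^2/s).
#' @param delta2 n+1 positive per-location error variances (m^2).
#' @param taus n positive time lags (s).
#' @return A [TribandedCovariance-class] of order n.
#' @export
buildIncrementCovariance <- function(sigma2, delta2, taus) {
  n <- length(sigma2)
  if (length(taus) != n || length(delta2) != n + 1L)
    .configError("need n sigma^2, n taus and n+1 delta^2")
  if (any(sigma2 <= 0) || any(delta2 <= 0) || any(taus <= 0))
    .dataError("variances and time lags must be strictly positive")
  new("TribandedCovariance",
      diag = sigma2 * taus + delta2[-(n + 1L)] + delta2[-1L],
      offdiag = -delta2[seq.int(2L, length.out = n - 1L)])
}

#' Origin-extended increment covariance
#'
#' Extends [buildIncrementCovariance()] by one leading row/column for the
#' deviation of the first observed location from the (estimated) trajectory
#' origin: its variance is `delta2[1]` and its covariance with the first
#' increment is `-delta2[1]`; the remaining block is the increment
#' covariance. The matrix stays tridiagonal, so evaluation remains O(n).
#'
#' @inheritParams buildIncrementCovariance
#' @return A [TribandedCovariance-class] of order n+1.
#' @export
buildOriginCovariance <- function(sigma2, delta2, taus) {
  inc <- buildIncrementCovariance(sigma2, delta2, taus)
  new("TribandedCovariance",
      diag = c(delta2[1L], inc@diag),
      offdiag = c(-delta2[1L], inc@offdiag))
}

#' @describeIn buildIncrementCovariance densify (for inspection/tests only;
#'   package code never materializes the dense matrix)
#' @param x a TribandedCovariance
#' @param ... ignored
#' @export
setMethod("as.matrix", "TribandedCovariance", function(x, ...) {
  k <- length(x@diag)
  M <- matrix(0, k, k)
  diag(M) <- x@diag
  if (k > 1L) {
    M[cbind(seq_len(k - 1L), 2:k)] <- x@offdiag
    M[cbind(2:k, seq_len(k - 1L))] <- x@offdiag
  }
  M
})

setMethod("show", "TribandedCovariance", function(object) {
  cat(sprintf("TribandedCovariance of order %d\n", length(object@diag)))
  cat("  diag   :", paste(signif(utils::head(object@diag, 5), 5), collapse = ", "),
      if (length(object@diag) > 5) "...", "\n")
  if (length(object@offdiag))
    cat("  offdiag:", paste(signif(utils::head(object@offdiag, 5), 5), collapse = ", "),
        if (length(object@offdiag) > 5) "...", "\n")
})

#' Exact Gaussian log-density under a tridiagonal covariance
#'
#' Evaluates `log N(x; 0, Sigma)` for symmetric tridiagonal `Sigma` through
#' its LDL' factorization in O(k) time and memory; no dense matrix is ever
#' formed. If `x` is a matrix, columns are treated as independent
#' realizations sharing `Sigma` (one factorization) and the log-densities
#' are summed — this is how the two coordinate axes of a track enter.
#'
#' A non-positive pivot (covariance not positive definite, e.g. from an
#' infeasible parameter vector) yields `-Inf` so optimizers and samplers
#' reject naturally instead of erroring.
#'
#' @param x numeric vector of length k, or k x c matrix.
#' @param cov a [TribandedCovariance-class].
#' @return scalar log-density (sum over columns), or `-Inf`.
#' @export
tridiagGaussianLogpdf <- function(x, cov) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(cov@diag))
    .configError("x length does not match covariance order")
  .tridiagLogpdfC(cov@diag, cov@offdiag, x)
}

#' Bundle a BBCM parameter vector
#'
#' @param betaSigma coefficients of the movement-variance design.
#' @param betaDelta coefficients of the error-variance design.
#' @param gamma optional (x, y) trajectory origin; omit (default) for the
#'   fixed-origin formulation in which only increments enter the likelihood.
#' @return A [BbcmParams-class].
#' @export
bbcmParams <- function(betaSigma, betaDelta, gamma = numeric(0)) {
  new("BbcmParams", betaSigma = as.numeric(betaSigma),
      betaDelta = as.numeric(betaDelta), gamma = as.numeric(gamma))
}

setMethod("show", "BbcmParams", function(object) {
  cat("BBCM parameters\n")
  cat("  beta_sigma2:", paste(signif(object@betaSigma, 5), collapse = ", "), "\n")
  cat("  beta_delta2:", paste(signif(object@betaDelta, 5), collapse = ", "), "\n")
  if (length(object@gamma))
    cat("  gamma      :", paste(signif(object@gamma, 6), collapse = ", "), "\n")
})

## Fast internal path: returns the variance vector or NULL if infeasible.
.varsOrNull <- function(mat, beta) {
  v <- drop(mat %*% beta)
  if (any(v <= 0) || anyNA(v)) NULL else v
}

#' BBCM log-likelihood of a trajectory
#'
#' Generates per-segment movement variances and per-location error
#' variances from the design matrices and coefficient vectors, then
#' evaluates the exact Gaussian log-likelihood of the increment vectors of
#' both coordinate axes (the axes are independent and share one covariance
#' — the model is isotropic). When `params` carries an origin `gamma`, the
#' deviation `Z_0 - gamma` of the first observed location is prepended and
#' the origin-extended covariance is used.
#'
#' Infeasible coefficients (any generated variance non-positive) give
#' `-Inf`.
#'
#' @param traj a [Trajectory-class].
#' @param design a [VarianceDesign-class] conforming to `traj`.
#' @param params a [BbcmParams-class].
#' @return scalar log-likelihood.
#' @export
bbcmLoglik <- function(traj, design, params) {
  n <- nSegments(traj)
  if (nrow(design@movementMatrix) != n)
    .configError("design does not conform to trajectory (row counts differ)")
  if (ncol(design@movementMatrix) != length(params@betaSigma) ||
      ncol(design@errorMatrix) != length(params@betaDelta))
    .configError("coefficient lengths do not match design columns")
  sigma2 <- .varsOrNull(design@movementMatrix, params@betaSigma)
  delta2 <- .varsOrNull(design@errorMatrix, params@betaDelta)
  if (is.null(sigma2) || is.null(delta2)) return(-Inf)
  taus <- timeLags(traj)
  deltas <- diff(traj@coords)
  odInner <- -delta2[seq.int(2L, length.out = n - 1L)]
  if (length(params@gamma)) {
    dg <- c(delta2[1L], sigma2 * taus + delta2[-(n + 1L)] + delta2[-1L])
    od <- c(-delta2[1L], odInner)
    X <- rbind(traj@coords[1L, ] - params@gamma, deltas)
  } else {
    dg <- sigma2 * taus + delta2[-(n + 1L)] + delta2[-1L]
    od <- odInner
    X <- deltas
  }
  .tridiagLogpdfC(dg, od, X)
}
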