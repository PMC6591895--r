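## covariate_design: term grammar, design-matrix construction, scaling,
## positivity bounds, and the hot-day spline duplication machinery.

.newTerm <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "bbcmTerm")
}

#' Model terms for variance designs
#'
#' A design is a list of terms per side (movement variance sigma^2 from
#' segment covariates; error variance delta^2 from location covariates).
#'
#' * `interceptTerm()` — a column of ones.
#' * `linearTerm(name)` — a continuous covariate, passed through (optionally
#'   centred/scaled by [scaleColumns()]).
#' * `factorTerm(name)` — treatment contrasts: the baseline level is
#'   absorbed by the intercept, the remaining levels get indicator columns.
#'   Factors use their declared level order (first level = baseline);
#'   character columns use order of first appearance with a lexicographic
#'   tie-break at equal first positions.
#' * `splineTerm(basis)` — a circular B-spline of time of day: on the
#'   movement side each basis function is averaged over the segment's time
#'   span, on the error side it is evaluated at the location's time. Because
#'   a full circular basis sums to one it absorbs the constant; combining it
#'   with a free intercept is rejected unless `separateConstant = TRUE`,
#'   which re-expresses the K columns as K-1 centred differences
#'   `B_j - B_K` so an explicit intercept can be identified.
#'
#' @param name covariate column name.
#' @param basis a [SplineBasis-class].
#' @param scale logical, whether [scaleColumns()] may touch this column.
#' @param separateConstant see above.
#' @return a term descriptor.
#' @name designTerms
NULL

#' @rdname designTerms
#' @export
interceptTerm <- function() .newTerm("intercept")

#' @rdname designTerms
#' @export
linearTerm <- function(name, scale = TRUE)
  .newTerm("linear", name = name, scale = isTRUE(scale))

#' @rdname designTerms
#' @export
factorTerm <- function(name) .newTerm("factor", name = name)

#' @rdname designTerms
#' @export
splineTerm <- function(basis, separateConstant = FALSE) {
  stopifnot(is(basis, "SplineBasis"))
  .newTerm("spline", basis = basis, separateConstant = isTRUE(separateConstant))
}

#' Specify a BBCM variance model
#'
#' @param movement list of terms generating per-segment sigma^2.
#' @param error list of terms generating per-location delta^2.
#' @return A validated [DesignSpec-class].
#' @examples
#' designSpec(
#'   movement = list(interceptTerm(), factorTerm("state"), linearTerm("mcov")),
#'   error = list(interceptTerm(), factorTerm("ecat"), linearTerm("ecov")))
#' @export
designSpec <- function(movement, error) {
  if (inherits(movement, "bbcmTerm")) movement <- list(movement)
  if (inherits(error, "bbcmTerm")) error <- list(error)
  new("DesignSpec", movementTerms = movement, errorTerms = error)
}

.factorLevels <- function(v) {
  if (is.factor(v)) return(levels(v))
  u <- unique(as.character(v))
  first <- match(u, as.character(v))
  u[order(first, u)]
}

.termColumns <- function(term, covs, traj, side) {
  switch(term$type,
    intercept = {
      nr <- if (side == "movement") nSegments(traj) else nLocations(traj)
      list(mat = matrix(1, nr, 1, dimnames = list(NULL, "(intercept)")),
           types = "intercept")
    },
    linear = {
      if (!term$name %in% names(covs))
        .configError(sprintf("unknown %s covariate '%s'", side, term$name))
      v <- covs[[term$name]]
      if (!is.numeric(v))
        .configError(sprintf("covariate '%s' must be numeric for a linear term", term$name))
      list(mat = matrix(v, ncol = 1, dimnames = list(NULL, term$name)),
           types = if (term$scale) "linear" else "linear_noscale")
    },
    factor = {
      if (!term$name %in% names(covs))
        .configError(sprintf("unknown %s covariate '%s'", side, term$name))
      v <- covs[[term$name]]
      lev <- .factorLevels(v)
      if (length(lev) < 2L)
        .configError(sprintf("factor '%s' has a single level", term$name))
      cols <- vapply(lev[-1], function(l) as.numeric(as.character(v) == l),
                     numeric(length(v)))
      colnames(cols) <- paste(term$name, lev[-1], sep = ".")
      list(mat = cols, types = rep("contrast", ncol(cols)))
    },
    spline = {
      tAbs <- trackTimes(traj, absolute = TRUE)
      B <- if (side == "movement") {
        segmentAverageSpline(term$basis, tAbs[-length(tAbs)], tAbs[-1])
      } else {
        evalSpline(term$basis, tAbs)
      }
      if (isTRUE(term$separateConstant)) {
        K <- ncol(B)
        B <- B[, -K, drop = FALSE] - B[, K]
        colnames(B) <- paste0("spline.d", seq_len(K - 1))
      } else {
        colnames(B) <- paste0("spline.", colnames(B))
      }
      list(mat = B, types = rep("spline", ncol(B)), basis = term$basis)
    },
    .configError(sprintf("unknown term type '%s'", term$type))
  )
}

#' Build the variance design matrices for a trajectory
#'
#' Expands a [DesignSpec-class] against a trajectory's covariate tables into
#' the n x m_sigma movement matrix and the (n+1) x m_delta error matrix
#' whose row-wise products with the coefficient vectors give the per-segment
#' movement variances and per-location error variances.
#'
#' @param traj a [Trajectory-class].
#' @param spec a [DesignSpec-class].
#' @return A [VarianceDesign-class] (unscaled; see [scaleColumns()]).
#' @export
buildDesign <- function(traj, spec) {
  validObject(spec)
  buildSide <- function(terms, covs, side) {
    parts <- lapply(terms, .termColumns, covs = covs, traj = traj, side = side)
    mat <- do.call(cbind, lapply(parts, `[[`, "mat"))
    types <- unlist(lapply(parts, `[[`, "types"))
    bases <- Filter(Negate(is.null), lapply(parts, `[[`, "basis"))
    list(mat = mat, types = types,
         basis = if (length(bases)) bases[[1]] else NULL)
  }
  mv <- buildSide(spec@movementTerms, segmentCovariates(traj), "movement")
  er <- buildSide(spec@errorTerms, locationCovariates(traj), "error")
  new("VarianceDesign",
      movementMatrix = mv$mat, errorMatrix = er$mat,
      movementTypes = mv$types, errorTypes = er$types,
      scaling = list(movement = NULL, error = NULL),
      movementBasis = mv$basis, errorBasis = er$basis)
}

#' @describeIn buildDesign the movement-side design matrix
#' @param design a VarianceDesign
#' @export
setMethod("movementMatrix", "VarianceDesign", function(design) design@movementMatrix)

#' @describeIn buildDesign the error-side design matrix
#' @export
setMethod("errorMatrix", "VarianceDesign", function(design) design@errorMatrix)

setMethod("show", "VarianceDesign", function(object) {
  cat(sprintf("VarianceDesign: %d segments\n", nrow(object@movementMatrix)))
  cat(sprintf("  movement (sigma^2): %d column(s): %s\n",
              ncol(object@movementMatrix),
              paste(colnames(object@movementMatrix), collapse = ", ")))
  cat(sprintf("  error   (delta^2): %d column(s): %s\n",
              ncol(object@errorMatrix),
              paste(colnames(object@errorMatrix), collapse = ", ")))
  if (!is.null(object@scaling$movement) || !is.null(object@scaling$error))
    cat("  continuous columns scaled (coefficients back-transformable)\n")
})

#' Centre and scale continuous design columns
#'
#' Continuous (linear) columns are divided by their standard deviation and,
#' when the side contains an intercept, centred; intercept, contrast and
#' spline columns are untouched. The transform record on the returned
#' design lets [backTransformBeta()] map coefficients exactly back to the
#' original covariate scale. Columns with zero variance are left unscaled
#' with a warning.
#'
#' @param design a [VarianceDesign-class].
#' @return The scaled design (with populated `scaling` record).
#' @export
scaleColumns <- function(design) {
  doSide <- function(mat, types) {
    m <- ncol(mat)
    center <- numeric(m)
    scl <- rep(1, m)
    hasInt <- any(types == "intercept")
    for (j in which(types == "linear")) {
      s <- stats::sd(mat[, j])
      if (!is.finite(s) || s == 0) {
        warning(sprintf("column '%s' has zero variance; left unscaled",
                        colnames(mat)[j]))
        next
      }
      if (hasInt) center[j] <- mean(mat[, j])
      scl[j] <- s
      mat[, j] <- (mat[, j] - center[j]) / s
    }
    list(mat = mat, rec = list(center = center, scale = scl))
  }
  mv <- doSide(design@movementMatrix, design@movementTypes)
  er <- doSide(design@errorMatrix, design@errorTypes)
  design@movementMatrix <- mv$mat
  design@errorMatrix <- er$mat
  design@scaling <- list(movement = mv$rec, error = er$rec)
  design
}

#' Map coefficients from the scaled to the original covariate scale
#'
#' For a column scaled as `(x - c)/s`, the fitted slope transforms as
#' `beta/s` and the intercept absorbs `-sum(beta_j c_j / s_j)`.
#'
#' @param design the SCALED [VarianceDesign-class] (from [scaleColumns()]).
#' @param beta coefficient vector estimated on the scaled design.
#' @param side `"movement"` or `"error"`.
#' @return coefficients on the original covariate scale.
#' @export
backTransformBeta <- function(design, beta, side = c("movement", "error")) {
  side <- match.arg(side)
  rec <- design@scaling[[side]]
  if (is.null(rec)) return(beta)
  types <- if (side == "movement") design@movementTypes else design@errorTypes
  out <- beta / rec$scale
  intIdx <- which(types == "intercept")
  if (length(intIdx))
    out[intIdx[1]] <- out[intIdx[1]] - sum(beta * rec$center / rec$scale)
  out
}

#' Variances generated by a design matrix and coefficient vector
#'
#' Row-wise dot products of the design matrix with `beta`. Variances must be
#' strictly positive; an infeasible coefficient vector raises a condition of
#' class `bbcmInfeasibleError` carrying the first offending row (`row`
#' field) rather than clamping.
#'
#' @param matrix rows x m design matrix.
#' @param beta m coefficients.
#' @return positive numeric vector, one variance per row.
#' @export
variancesFromDesign <- function(matrix, beta) {
  if (ncol(matrix) != length(beta))
    .configError("design matrix and beta dimensions disagree")
  v <- drop(matrix %*% beta)
  bad <- which(v <= 0)
  if (length(bad)) {
    cond <- structure(
      class = c("bbcmInfeasibleError", "error", "condition"),
      list(message = sprintf(
        "coefficients generate a non-positive variance at row %d (value %.6g); all variance estimates need to be positive",
        bad[1], v[bad[1]]), call = sys.call(-1), row = bad[1]))
    stop(cond)
  }
  v
}

#' Feasibility bound for the leading coefficient
#'
#' With the remaining coefficients fixed, positivity of every generated
#' variance constrains the first coefficient to one side of a bound that
#' depends on the design rows; it can therefore be computed during sampling
#' or optimisation. Requires the first column to be strictly positive or
#' strictly negative (e.g. an intercept).
#'
#' @param matrix rows x m design matrix.
#' @param betaOthers the other m-1 coefficients (columns 2..m).
#' @return the tight bound, with attribute `direction` equal to
#'   `"greater"` (first column positive: feasible iff beta1 > bound) or
#'   `"less"` (first column negative: feasible iff beta1 < bound).
#' @export
interceptFeasibleBound <- function(matrix, betaOthers) {
  x1 <- matrix[, 1]
  if (all(x1 > 0)) dirn <- "greater"
  else if (all(x1 < 0)) dirn <- "less"
  else .configError("first design column must be strictly positive or strictly negative")
  rest <- if (ncol(matrix) > 1L)
    drop(matrix[, -1, drop = FALSE] %*% betaOthers) else numeric(nrow(matrix))
  ratio <- -rest / x1
  bound <- if (dirn == "greater") max(ratio) else min(ratio)
  structure(bound, direction = dirn)
}

#' Duplicate spline columns inside a time window for a segment subset
#'
#' Implements interaction of a daily activity spline with a day-type factor
#' restricted to a window (e.g. "different late-morning activity on hot
#' days"): the basis columns whose maximum lies inside the window are
#' copied; copies are multiplied by the 0/1 segment indicator and the
#' originals by its complement, so the two day types get independent
#' coefficients within the window and share coefficients elsewhere. The
#' peak of each basis function is located by an argmax scan on a 1-minute
#' grid of the period.
#'
#' @param design a [VarianceDesign-class] whose movement side contains a
#'   spline term.
#' @param indicator logical/0-1 vector of length n flagging the segments of
#'   the second regime (e.g. hot days).
#' @param window numeric `c(start, end)` in seconds of the period (e.g.
#'   `c(9, 12) * 3600` for 09:00-12:00).
#' @return The extended [VarianceDesign-class]; new columns are named after
#'   the originals with suffix `".dup"`.
#' @export
duplicateSplineColumns <- function(design, indicator, window) {
  basis <- design@movementBasis
  if (is.null(basis))
    .configError("design has no movement-side spline term to duplicate")
  indicator <- as.numeric(indicator)
  if (length(indicator) != nrow(design@movementMatrix))
    .configError("indicator must have one entry per segment")
  if (!all(indicator %in% c(0, 1)))
    .configError("indicator must be logical or 0/1")
  grid <- seq(0, basis@period, by = 60)
  B <- evalSpline(basis, grid)
  peaks <- grid[apply(B, 2, which.max)]
  inWin <- peaks >= window[1] & peaks < window[2]
  if (!any(inWin))
    .configError("no spline basis function peaks inside the given window")
  splineCols <- which(design@movementTypes == "spline")
  if (length(splineCols) != nBasis(basis))
    .configError("spline duplication requires the full (non-separated) basis columns")
  dupCols <- splineCols[inWin]
  M <- design@movementMatrix
  newCols <- M[, dupCols, drop = FALSE] * indicator
  colnames(newCols) <- paste0(colnames(M)[dupCols], ".dup")
  M[, dupCols] <- M[, dupCols, drop = FALSE] * (1 - indicator)
  design@movementMatrix <- cbind(M, newCols)
  design@movementTypes <- c(design@movementTypes,
                            rep("spline", length(dupCols)))
  validObject(design)
  design
}
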