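## Circular cubic B-spline bases for periodic (daily) activity patterns.
##
## The basis is built on an unwrapped axis with knots replicated one period
## to each side (splines::splineDesign does the piecewise-polynomial work);
## wrap-around is obtained by summing the ordinary B-splines that are one
## period apart, which yields exactly K periodic basis functions for K
## circle knots, non-negative and summing to one everywhere.

#' Create a circular cubic B-spline basis
#'
#' @param knots K strictly increasing knot positions in `[0, period)`,
#'   K >= 4. Non-uniform placement concentrates flexibility where data
#'   exist (e.g. daytime-only tracking).
#' @param period circle circumference in seconds; default one day (86400).
#' @return A [SplineBasis-class].
#' @examples
#' b <- splineBasis(seq(0, 86400, length.out = 7)[-7])
#' rowSums(evalSpline(b, c(0, 3600, 86399)))  # partition of unity
#' @export
splineBasis <- function(knots, period = 86400) {
  new("SplineBasis", period = as.numeric(period),
      knots = as.numeric(sort(knots)), degree = 3L)
}

#' Uniformly spaced circular basis
#'
#' @param k number of knots/basis functions (>= 4).
#' @param period circle circumference, seconds.
#' @export
uniformSplineBasis <- function(k, period = 86400) {
  splineBasis(seq(0, period, length.out = k + 1)[seq_len(k)], period)
}

#' @describeIn splineBasis number of basis functions K
#' @param basis a SplineBasis
#' @export
setMethod("nBasis", "SplineBasis", function(basis) length(basis@knots))

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf("Circular cubic B-spline basis: %d knots on period %.0f s\n",
              length(object@knots), object@period))
  cat("  knots (s):", paste(signif(object@knots, 6), collapse = ", "), "\n")
})

## Extended knot sequence: one replication of the circle knots per side.
.extKnots <- function(basis) {
  k <- basis@knots
  c(k - basis@period, k, k + basis@period)
}

## Reduce times to phase in [k1, k1 + P) where the unwrapped basis is
## evaluated.
.wrapPhase <- function(basis, t) {
  k1 <- basis@knots[1]
  ((t - k1) %% basis@period) + k1
}

#' Evaluate the periodic basis
#'
#' Returns the instantaneous basis values B_j(t mod period). All values lie
#' in `[0, 1]` and each row sums to 1.
#'
#' @param basis a [SplineBasis-class].
#' @param t numeric vector of times (seconds); any real values.
#' @return numeric matrix `length(t) x K`.
#' @export
setMethod("evalSpline", "SplineBasis", function(basis, t) {
  K <- length(basis@knots)
  ts <- .wrapPhase(basis, t)
  M <- splines::splineDesign(.extKnots(basis), ts, ord = 4L, outer.ok = TRUE)
  B <- M[, (K + 1):(2 * K), drop = FALSE]
  ## wrap-around: basis functions whose support crosses the period boundary
  ## pick up the copy one period earlier
  for (j in seq.int(max(1L, K - 3L), K))
    B[, j] <- B[, j] + M[, j]
  dimnames(B) <- list(NULL, paste0("b", seq_len(K)))
  B
})

## Gauss-Legendre nodes/weights on [-1, 1], computed once via the
## Golub-Welsch eigenvalue method. 21 nodes are exact far beyond cubic, so
## knot-split quadrature integrates the basis exactly up to round-off.
.gaussLegendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  E <- eigen(.symTridiag(n, b), symmetric = TRUE)
  list(nodes = E$values, weights = 2 * E$vectors[1, ]^2)
}

.symTridiag <- function(n, b) {
  A <- matrix(0, n, n)
  if (n > 1L) {
    A[cbind(seq_len(n - 1), 2:n)] <- b
    A[cbind(2:n, seq_len(n - 1))] <- b
  }
  A
}

.glCache <- new.env(parent = emptyenv())
.gl <- function(n) {
  key <- as.character(n)
  if (is.null(.glCache[[key]])) .glCache[[key]] <- .gaussLegendre(n)
  .glCache[[key]]
}

## Integrals of every basis function over one full period. By symmetry of
## the construction this equals the integral of one ordinary cubic B-spline
## over its support, but it is computed by the same knot-split quadrature
## used everywhere else.
.periodIntegrals <- function(basis) {
  k1 <- basis@knots[1]
  .openIntegrals(basis, k1, k1 + basis@period)
}

## Integral of each basis function over [a, b] with
## [a, b] inside [k1, k1 + P]; split at interior knots, 21-node GL per span.
.openIntegrals <- function(basis, a, b, nodes = 21L) {
  brk <- .extKnots(basis)
  cuts <- sort(unique(c(a, b, brk[brk > a & brk < b])))
  gl <- .gl(nodes)
  out <- numeric(length(basis@knots))
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    h <- (hi - lo) / 2
    tt <- lo + h * (gl$nodes + 1)
    out <- out + h * colSums(gl$weights * evalSpline(basis, tt))
  }
  out
}

#' Segment-averaged basis values
#'
#' The movement variance coefficient of a segment represents the whole
#' interval between its two locations, so periodic covariates enter the
#' design matrix as the time average of each basis function over the
#' segment: `(1/(t1-t0)) * integral of B_j(t mod P) dt`. Intervals longer
#' than one period are reduced to whole-period integrals plus a remainder;
#' within a period the integral is split at knots and evaluated by fixed
#' 21-node Gauss-Legendre quadrature per span (exact for cubics).
#'
#' @param basis a [SplineBasis-class].
#' @param tStart,tEnd interval endpoints (seconds), `tEnd > tStart`;
#'   vectors of equal length are averaged element-wise.
#' @return numeric matrix `length(tStart) x K`; each row sums to 1.
#' @export
setMethod("segmentAverageSpline", "SplineBasis", function(basis, tStart, tEnd) {
  tStart <- as.numeric(tStart); tEnd <- as.numeric(tEnd)
  if (length(tStart) != length(tEnd))
    .configError("tStart and tEnd must have equal length")
  if (any(tEnd <= tStart))
    .configError("segment averaging requires tEnd > tStart for every interval")
  P <- basis@period
  K <- length(basis@knots)
  len <- tEnd - tStart
  full <- floor(len / P)
  rem <- len - full * P
  a <- .wrapPhase(basis, tStart)          # in [k1, k1 + P)
  k1 <- basis@knots[1]
  perInt <- .periodIntegrals(basis)
  ## remainder splits into at most two arcs of the unwrapped axis:
  ## [a, min(a + rem, k1 + P)] and, if it wraps, [k1, a + rem - P]
  hi1 <- pmin(a + rem, k1 + P)
  hasWrap <- (a + rem) > (k1 + P + 1e-9)
  hi2 <- a + rem - P
  segIdx <- c(seq_along(a), which(hasWrap))
  lo <- c(a, rep(k1, sum(hasWrap)))
  hi <- c(hi1, hi2[hasWrap])
  keep <- (hi - lo) > 1e-12
  integ <- matrix(0, length(a), K)
  if (any(keep))
    integ <- integ + .batchIntegrals(basis, lo[keep], hi[keep], segIdx[keep],
                                     length(a))
  integ <- integ + outer(full, perInt)
  out <- integ / len
  dimnames(out) <- list(NULL, paste0("b", seq_len(K)))
  out
})

## Vectorized knot-split GL integration of many arcs at once: one
## splineDesign call for all quadrature nodes, then a weighted rowsum.
.batchIntegrals <- function(basis, lo, hi, segIdx, nSeg, nodes = 21L) {
  brk <- .extKnots(basis)
  gl <- .gl(nodes)
  pieceLo <- list(); pieceHi <- list(); pieceSeg <- list()
  for (i in seq_along(lo)) {
    cuts <- sort(unique(c(lo[i], hi[i], brk[brk > lo[i] & brk < hi[i]])))
    m <- length(cuts) - 1L
    pieceLo[[i]] <- cuts[-(m + 1L)]
    pieceHi[[i]] <- cuts[-1L]
    pieceSeg[[i]] <- rep.int(segIdx[i], m)
  }
  plo <- unlist(pieceLo); phi <- unlist(pieceHi); pseg <- unlist(pieceSeg)
  h <- (phi - plo) / 2
  tt <- rep(plo, each = nodes) + rep(h, each = nodes) * (gl$nodes + 1)
  w <- rep(h, each = nodes) * gl$weights
  B <- evalSpline(basis, tt) * w
  g <- rep(pseg, each = nodes)
  out <- matrix(0, nSeg, length(basis@knots))
  agg <- rowsum(B, group = g)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
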