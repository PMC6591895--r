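## utilization_distribution: Brownian-bridge occupancy density on a regular
## grid from fitted per-segment sigma^2 and per-location delta^2.

#' Brownian-bridge position moments within a segment
#'
#' At fraction `alpha` of segment `i`, the position given the two observed
#' anchor locations is Gaussian with mean on the straight line between them
#' and isotropic variance combining bridge diffusion and the (error) spread
#' of both anchors:
#' `tau_i * alpha * (1-alpha) * sigma2_i + (1-alpha)^2 * delta2_i + alpha^2 *
#' delta2_{i+1}`.
#'
#' @param traj a [Trajectory-class].
#' @param i segment index (1..n).
#' @param alpha fraction(s) in `[0, 1]`.
#' @param sigma2i segment movement variance (m^2/s).
#' @param delta2i,delta2ip1 error variances at the two anchor locations.
#' @return list with `mean` (length(alpha) x 2 matrix) and `var`
#'   (length(alpha) vector, per axis).
#' @export
bridgeMoments <- function(traj, i, alpha, sigma2i, delta2i, delta2ip1) {
  if (any(alpha < 0 | alpha > 1)) .configError("alpha must lie in [0, 1]")
  z <- traj@coords
  tau <- timeLags(traj)[i]
  mean <- cbind(z[i, 1] + alpha * (z[i + 1, 1] - z[i, 1]),
                z[i, 2] + alpha * (z[i + 1, 2] - z[i, 2]))
  var <- tau * alpha * (1 - alpha) * sigma2i +
    (1 - alpha)^2 * delta2i + alpha^2 * delta2ip1
  list(mean = mean, var = var)
}

#' Compute the utilization distribution on a regular grid
#'
#' The UD is the time-weighted average over (selected) segments of the
#' Brownian-bridge position density, integrated over the within-segment
#' fraction alpha by fixed 30-node Gauss-Legendre quadrature:
#' `UD(cell) propto sum_i tau_i integral_0^1 N(cell; mean_i(alpha),
#' var_i(alpha) I) dalpha`, anchored on the observed positions. Cell masses
#' are density times cell area, renormalized to 1 over the grid.
#'
#' The segment mask supports conditional UDs (e.g. hot-day vs cool-day
#' space use) and excluding very long gap-spanning segments.
#'
#' @param traj a [Trajectory-class].
#' @param sigma2 n positive per-segment movement variances.
#' @param delta2 n+1 positive per-location error variances.
#' @param cellSize grid cell edge (m); default 1/200 of the largest
#'   bounding-box extent (after margin).
#' @param margin extra grid border beyond the location bounding box (m);
#'   default three standard deviations of the largest bridge variance.
#' @param segmentMask optional logical vector of length n selecting
#'   segments.
#' @param nAlpha quadrature nodes per segment.
#' @param maxCells refuse grids larger than this (ask for larger cells).
#' @return A [UDGrid-class].
#' @export
computeUd <- function(traj, sigma2, delta2, cellSize = NULL, margin = NULL,
                      segmentMask = NULL, nAlpha = 30L, maxCells = 4e6) {
  n <- nSegments(traj)
  if (length(sigma2) != n || length(delta2) != n + 1L)
    .configError("need n sigma^2 and n+1 delta^2 values")
  if (any(sigma2 <= 0) || any(delta2 <= 0))
    .dataError("variances must be positive")
  if (is.null(segmentMask)) segmentMask <- rep(TRUE, n)
  if (length(segmentMask) != n) .configError("segmentMask must have length n")
  if (!any(segmentMask)) .configError("segment mask selects no segments")
  taus <- timeLags(traj)
  sel <- which(segmentMask)
  vmax <- max(taus[sel] * sigma2[sel] / 4 +
              pmax(delta2[sel], delta2[sel + 1L]))
  if (is.null(margin)) margin <- 3 * sqrt(vmax)
  z <- traj@coords
  xr <- range(z[, 1]) + c(-margin, margin)
  yr <- range(z[, 2]) + c(-margin, margin)
  if (is.null(cellSize)) cellSize <- max(diff(xr), diff(yr)) / 200
  nx <- max(2L, ceiling(diff(xr) / cellSize))
  ny <- max(2L, ceiling(diff(yr) / cellSize))
  if (as.double(nx) * ny > maxCells)
    .configError(sprintf(
      "grid would have %.0f cells (> %g); use a larger cellSize",
      as.double(nx) * ny, maxCells))
  x <- xr[1] + (seq_len(nx) - 0.5) * cellSize
  y <- yr[1] + (seq_len(ny) - 0.5) * cellSize
  gl <- .gl(nAlpha)
  alpha <- (gl$nodes + 1) / 2
  wAlpha <- gl$weights / 2
  dens <- matrix(0, nx, ny)
  for (i in sel) {
    bm <- bridgeMoments(traj, i, alpha, sigma2[i], delta2[i], delta2[i + 1L])
    sdv <- sqrt(bm$var)
    for (q in seq_len(nAlpha)) {
      dens <- dens + (taus[i] * wAlpha[q]) *
        outer(stats::dnorm(x, bm$mean[q, 1], sdv[q]),
              stats::dnorm(y, bm$mean[q, 2], sdv[q]))
    }
  }
  mass <- dens * cellSize^2
  total <- sum(mass)
  if (total < 0.95)
    warning(sprintf(
      "only %.1f%% of the UD mass falls on the grid; increase the margin",
      100 * total))
  new("UDGrid", x = x, y = y, mass = mass / total, cellSize = cellSize)
}

setMethod("show", "UDGrid", function(object) {
  cat(sprintf("UDGrid: %d x %d cells of %.2f m\n",
              length(object@x), length(object@y), object@cellSize))
  cat(sprintf("  total mass %.6f; max cell mass %.3g\n",
              sum(object@mass), max(object@mass)))
})

#' Highest-density contour of a UD
#'
#' Cells are sorted by mass (descending); the contour set is the smallest
#' set of cells whose cumulative mass reaches `p`. Ties at the threshold
#' mass are broken deterministically by cell index, so a uniform grid at
#' `p = 0.5` yields exactly half its cells. This is the usual volume
#' contour used for 50%/95% space-use isopleths.
#'
#' @param ud a [UDGrid-class].
#' @param p probability in (0, 1).
#' @return list with `threshold` (mass of the last included cell), `mask`
#'   (logical cell matrix), `level` (= p) and `massCovered`.
#' @export
contourThreshold <- function(ud, p) {
  if (p <= 0 || p >= 1) .configError("p must be in (0, 1)")
  ord <- order(as.vector(ud@mass), decreasing = TRUE)
  v <- as.vector(ud@mass)[ord]
  kmin <- which(cumsum(v) >= p - 1e-12)[1]
  mask <- matrix(FALSE, nrow(ud@mass), ncol(ud@mass))
  mask[ord[seq_len(kmin)]] <- TRUE
  list(threshold = v[kmin], mask = mask, level = p,
       massCovered = sum(ud@mass[mask]))
}

#' Write a UD as CSV (x, y, mass)
#'
#' @param ud a [UDGrid-class].
#' @param path output path.
#' @export
writeUdCsv <- function(ud, path) {
  df <- expand.grid(x = ud@x, y = ud@y)
  df$mass <- as.vector(ud@mass)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a UD as an ESRI ASCII grid
#'
#' @param ud a [UDGrid-class].
#' @param path output path.
#' @export
writeUdAsciiGrid <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nx <- length(ud@x); ny <- length(ud@y)
  writeLines(c(
    sprintf("ncols %d", nx),
    sprintf("nrows %d", ny),
    sprintf("xllcorner %.10g", ud@x[1] - ud@cellSize / 2),
    sprintf("yllcorner %.10g", ud@y[1] - ud@cellSize / 2),
    sprintf("cellsize %.10g", ud@cellSize),
    "NODATA_value -9999"), con)
  for (j in rev(seq_len(ny)))
    writeLines(paste(format(ud@mass[, j], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}
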