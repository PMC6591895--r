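## trajectory_core: the Trajectory data model and delimited-text IO.

.bbcmError <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.configError <- function(msg) .bbcmError(msg, "bbcmConfigError")
.dataError <- function(msg) .bbcmError(msg, "bbcmDataError")

#' Construct a Trajectory
#'
#' @param times numeric seconds (relative or absolute/epoch) or POSIXct,
#'   strictly increasing, length n+1.
#' @param coords (n+1) x 2 matrix (or two-column data.frame) of planar
#'   coordinates in metres.
#' @param locationCovariates optional data.frame, one row per location.
#' @param segmentCovariates optional data.frame, one row per segment; values
#'   represent the whole interval between the two bounding locations.
#' @return A validated [Trajectory-class].
#' @export
trajectory <- function(times, coords, locationCovariates = NULL,
                       segmentCovariates = NULL) {
  if (inherits(times, "POSIXt")) times <- as.numeric(times)
  times <- as.numeric(times)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  np1 <- length(times)
  if (is.null(locationCovariates)) locationCovariates <- .emptyDf(np1)
  if (is.null(segmentCovariates)) segmentCovariates <- .emptyDf(np1 - 1L)
  origin <- if (np1) times[1] else 0
  new("Trajectory",
      times = times - origin, coords = coords, timeOrigin = origin,
      locationCovariates = locationCovariates,
      segmentCovariates = segmentCovariates)
}

#' @describeIn trajectory number of segments n
#' @param x a Trajectory
#' @export
setMethod("nSegments", "Trajectory", function(x) length(x@times) - 1L)

#' @describeIn trajectory number of locations n+1
#' @export
setMethod("nLocations", "Trajectory", function(x) length(x@times))

#' @describeIn trajectory observation times; `absolute = TRUE` adds back the
#'   time origin (needed for time-of-day phases)
#' @param absolute logical
#' @export
setMethod("trackTimes", "Trajectory", function(x, absolute = FALSE) {
  if (absolute) x@times + x@timeOrigin else x@times
})

#' @describeIn trajectory the (n+1) x 2 coordinate matrix
#' @export
setMethod("trackCoords", "Trajectory", function(x) x@coords)

#' @describeIn trajectory time lags tau_i = t_{i+1} - t_i
#' @export
setMethod("timeLags", "Trajectory", function(x) diff(x@times))

#' @describeIn trajectory per-location covariate table
#' @export
setMethod("locationCovariates", "Trajectory", function(x) x@locationCovariates)

#' @describeIn trajectory per-segment covariate table
#' @export
setMethod("segmentCovariates", "Trajectory", function(x) x@segmentCovariates)

setMethod("show", "Trajectory", function(object) {
  n <- nSegments(object)
  cat(sprintf("Trajectory: %d locations (%d segments), duration %.1f s\n",
              n + 1L, n, object@times[n + 1L]))
  cat(sprintf("  mean time lag %.2f s; bounding box x [%.1f, %.1f], y [%.1f, %.1f]\n",
              mean(diff(object@times)),
              min(object@coords[, 1]), max(object@coords[, 1]),
              min(object@coords[, 2]), max(object@coords[, 2])))
  lc <- names(object@locationCovariates)
  sc <- names(object@segmentCovariates)
  if (length(lc)) cat("  location covariates:", paste(lc, collapse = ", "), "\n")
  if (length(sc)) cat("  segment covariates: ", paste(sc, collapse = ", "), "\n")
})

.parseTimes <- function(v, path) {
  if (is.numeric(v)) return(as.numeric(v))
  tt <- suppressWarnings(as.numeric(v))
  if (!anyNA(tt)) return(tt)
  p <- as.POSIXct(v, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
  if (anyNA(p))
    .dataError(sprintf("unparseable timestamps in %s (expect ISO-8601 or epoch seconds)", path))
  as.numeric(p)
}

.geoLike <- function(nm) grepl("^(lon|lng|longitude|lat|latitude)$", tolower(nm))

#' Read a trajectory from delimited text
#'
#' Reads a CSV (header required) with one row per location. Default columns
#' are `timestamp`, `x` and `y`; any further columns are attached as
#' covariates. Rows are sorted by time; duplicate timestamps are rejected.
#' Geographic coordinates (columns named like lon/lat) are rejected rather
#' than reprojected: the model works in a planar metric frame and the
#' projection is the caller's responsibility.
#'
#' @param path file path.
#' @param columnMap named list mapping roles to column names, e.g.
#'   `list(timestamp = "t", x = "easting", y = "northing")`.
#' @param segmentCols character: names of covariate columns to treat as
#'   per-segment (row i describes the interval starting at location i; the
#'   value on the last row is ignored). All other extra columns become
#'   per-location covariates.
#' @param sep field separator, default comma.
#' @return A [Trajectory-class].
#' @export
readTrajectory <- function(path,
                           columnMap = list(timestamp = "timestamp", x = "x", y = "y"),
                           segmentCols = character(), sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- unlist(columnMap[c("timestamp", "x", "y")])
  missing <- setdiff(need, names(df))
  if (length(missing))
    .configError(paste("missing mapped column(s):", paste(missing, collapse = ", ")))
  if (any(.geoLike(need[c("x", "y")])))
    .configError("geographic (lon/lat) coordinates are not supported; project to a planar metric CRS first")
  times <- .parseTimes(df[[need[["timestamp"]]]], path)
  ord <- order(times)
  df <- df[ord, , drop = FALSE]
  times <- times[ord]
  dup <- which(diff(times) == 0)
  if (length(dup))
    .dataError(sprintf("duplicate timestamp at row %d of %s (after sorting)",
                       dup[1] + 1L, path))
  coords <- cbind(as.numeric(df[[need[["x"]]]]), as.numeric(df[[need[["y"]]]]))
  extra <- setdiff(names(df), need)
  missingSeg <- setdiff(segmentCols, extra)
  if (length(missingSeg))
    .configError(paste("segment covariate column(s) not in file:",
                       paste(missingSeg, collapse = ", ")))
  locCols <- setdiff(extra, segmentCols)
  np1 <- length(times)
  loc <- df[locCols]
  seg <- df[seq_len(np1 - 1L), segmentCols, drop = FALSE]
  rownames(loc) <- NULL
  rownames(seg) <- NULL
  for (nm in names(loc)) if (anyNA(loc[[nm]]))
    .dataError(sprintf(
      "missing values in covariate '%s' (row %d); segment covariates need to be listed in segmentCols",
      nm, which(is.na(loc[[nm]]))[1]))
  for (nm in names(seg)) if (anyNA(seg[[nm]]))
    .dataError(sprintf("missing values in segment covariate '%s' (row %d)",
                       nm, which(is.na(seg[[nm]]))[1]))
  trajectory(times, coords, loc, seg)
}

#' Write a trajectory as CSV
#'
#' Inverse of [readTrajectory()]: location covariates are written as-is,
#' segment covariates are padded with an empty last row (they have n rows
#' for n+1 locations). Absolute times are written so a round trip preserves
#' time-of-day phase.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return invisibly, the written data.frame.
#' @export
writeTrajectory <- function(traj, path) {
  np1 <- nLocations(traj)
  out <- data.frame(timestamp = trackTimes(traj, absolute = TRUE),
                    x = traj@coords[, 1], y = traj@coords[, 2])
  lc <- locationCovariates(traj)
  if (ncol(lc)) out <- cbind(out, lc)
  sc <- segmentCovariates(traj)
  if (ncol(sc)) {
    pad <- sc[1, , drop = FALSE]
    pad[1, ] <- NA
    out <- cbind(out, rbind(sc, pad))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}

#' Increments of a trajectory
#'
#' The n coordinate differences X_i between consecutive observed locations,
#' together with their time lags. These are the data entering the model
#' likelihood: under the model the increment vector per axis is zero-mean
#' Gaussian with a symmetric tridiagonal covariance, because adjacent
#' increments share the measurement error of their common location.
#'
#' @param traj a [Trajectory-class].
#' @return An [Increments-class].
#' @export
setMethod("computeIncrements", "Trajectory", function(traj) {
  n <- nSegments(traj)
  if (n < 1L) .dataError("trajectory has no segments")
  new("Increments",
      deltas = diff(traj@coords),
      taus = diff(traj@times))
})
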