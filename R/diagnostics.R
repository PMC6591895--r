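## inference_engine (part 3): convergence diagnostics, intervals, AIC.

## Classic split R-hat (potential scale reduction on half-chains): each
## chain is halved, then the usual between/within variance ratio is
## computed over the 2C half-chains. Values near 1 indicate mixing; above
## 1.1 a poorly fitting model/sampler.
.splitRhatMatrix <- function(x) {
  ## x: iterations x chains for one parameter
  nIter <- nrow(x)
  nh <- nIter %/% 2L
  if (nh < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(nh), , drop = FALSE],
                  x[nh + seq_len(nh), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- nh * stats::var(means)
  if (W == 0) return(if (B > 0) Inf else NA_real_)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Split R-hat convergence diagnostic
#'
#' @param chains a [PosteriorChains-class] or an
#'   `[iteration, chain, parameter]` array with at least 2 chains and 4
#'   draws per chain.
#' @return named numeric vector of split R-hat values, one per parameter;
#'   `NA` where the within-chain variance is zero and there is no
#'   between-chain variance (undefined), `Inf` for frozen chains stuck at
#'   distinct values.
#' @export
setMethod("splitRhat", "PosteriorChains", function(chains) {
  r <- splitRhat(chains@draws)
  names(r) <- chains@parameterNames
  r
})

#' @rdname splitRhat
#' @export
setMethod("splitRhat", "array", function(chains) {
  d <- dim(chains)
  if (length(d) != 3L) .configError("expected an [iteration, chain, parameter] array")
  if (d[2] < 2L) .configError("split R-hat needs at least 2 chains")
  if (d[1] < 4L) .configError("split R-hat needs at least 4 draws per chain")
  vapply(seq_len(d[3]), function(p) .splitRhatMatrix(chains[, , p]),
         numeric(1))
})

#' Central posterior intervals
#'
#' Pooled-across-chains central quantile intervals per parameter.
#'
#' @param chains a [PosteriorChains-class].
#' @param levels interval masses, default 50% and 95%.
#' @return data.frame with columns `parameter`, `level`, `lower`, `median`,
#'   `upper`.
#' @export
setMethod("posteriorIntervals", "PosteriorChains",
          function(chains, levels = c(0.5, 0.95)) {
  pooled <- posteriorDraws(chains, pooled = TRUE)
  out <- do.call(rbind, lapply(levels, function(lv) {
    a <- (1 - lv) / 2
    data.frame(
      parameter = colnames(pooled),
      level = lv,
      lower = apply(pooled, 2, stats::quantile, probs = a, names = FALSE),
      median = apply(pooled, 2, stats::quantile, probs = 0.5, names = FALSE),
      upper = apply(pooled, 2, stats::quantile, probs = 1 - a, names = FALSE),
      row.names = NULL)
  }))
  out
})

#' Compare fitted models by AIC
#'
#' Orders fits of the SAME trajectory by AIC (ties broken in favour of
#' fewer parameters) and reports differences to the best model.
#'
#' @param ... [FitResult-class] objects, or a single list of them.
#' @return data.frame `model`, `logLik`, `k`, `aic`, `dAic`, best first.
#' @export
compareAic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !is(fits[[1]], "FitResult"))
    fits <- fits[[1]]
  if (!all(vapply(fits, is, TRUE, class2 = "FitResult")))
    .configError("compareAic expects FitResult objects")
  if (length(fits) > 1L) {
    fp <- fits[[1]]@fingerprint
    same <- vapply(fits, function(f)
      isTRUE(all.equal(f@fingerprint, fp, tolerance = 1e-8)), TRUE)
    if (!all(same))
      .configError("AIC comparison requires fits of the same trajectory")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f@modelLabel, character(1)),
    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
    k = vapply(fits, function(f) f@nParams, integer(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1)))
  tab <- tab[order(tab$aic, tab$k), , drop = FALSE]
  tab$dAic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Serialize a fit as JSON
#'
#' @param fit a [FitResult-class].
#' @param path output path.
#' @param maxRhat optional maximal split R-hat to record alongside.
#' @export
writeFitJson <- function(fit, path, maxRhat = NULL) {
  obj <- list(
    model = fit@modelLabel,
    parameters = as.list(coefficients(fit)),
    logLik = fit@logLik, aic = fit@aic, k = fit@nParams,
    convergence = fit@convergence, scaled = fit@scaled)
  if (!is.null(maxRhat)) obj$maxRhat <- maxRhat
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write raw MCMC draws as CSV
#'
#' One row per retained draw; parameter columns plus `chain` and `iter`.
#'
#' @param chains a [PosteriorChains-class].
#' @param path output path.
#' @export
writeChainsCsv <- function(chains, path) {
  d <- dim(chains@draws)
  df <- as.data.frame(posteriorDraws(chains, pooled = TRUE))
  df$chain <- rep(seq_len(d[2]), each = d[1])
  df$iter <- rep(seq_len(d[1]), times = d[2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
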