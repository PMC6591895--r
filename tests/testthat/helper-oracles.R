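# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense linear algebra instead of banded, a
# textbook Cox-de Boor recursion instead of splines::splineDesign, and a
# direct transcription of the split R-hat formula.

# dense multivariate normal log-density at mean zero
denseMvnLogpdf <- function(x, Sigma) {
  x <- as.matrix(x)
  k <- nrow(x)
  R <- chol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  quad <- sum(backsolve(R, x, transpose = TRUE)^2)
  -0.5 * (ncol(x) * k * log(2 * pi) + ncol(x) * logdet + quad)
}

# textbook Cox-de Boor recursion: B-spline basis function i (0-based knot
# interval indexing) of order k on knot vector kn, evaluated at scalar t
coxDeBoor <- function(t, i, k, kn) {
  if (k == 1)
    return(as.numeric(t >= kn[i] & t < kn[i + 1]))
  w1 <- if (kn[i + k - 1] > kn[i])
    (t - kn[i]) / (kn[i + k - 1] - kn[i]) else 0
  w2 <- if (kn[i + k] > kn[i + 1])
    (kn[i + k] - t) / (kn[i + k] - kn[i + 1]) else 0
  w1 * coxDeBoor(t, i, k - 1, kn) + w2 * coxDeBoor(t, i + 1, k - 1, kn)
}

# periodic basis value by summing all shifted copies of the ordinary
# B-spline built by the recursion above
periodicBasisOracle <- function(basis, t) {
  P <- basis@period
  kn <- basis@knots
  K <- length(kn)
  ext <- c(kn - 2 * P, kn - P, kn, kn + P, kn + 2 * P)
  tw <- ((t - kn[1]) %% P) + kn[1]
  out <- matrix(0, length(t), K)
  for (j in seq_len(K)) {
    idx <- j + K * (0:3)              # copies of circle knot j in ext
    for (ii in idx[idx + 4 <= length(ext)]) {
      out[, j] <- out[, j] +
        vapply(tw, coxDeBoor, numeric(1), i = ii, k = 4, kn = ext)
    }
  }
  out
}

# split R-hat transcribed directly from the half-chain formulation
splitRhatOracle <- function(x) {
  # x: iterations x chains
  nh <- nrow(x) %/% 2
  halves <- cbind(x[1:nh, , drop = FALSE],
                  x[nh + (1:nh), , drop = FALSE])
  psibar <- colMeans(halves)
  s2 <- apply(halves, 2, var)
  W <- mean(s2)
  B <- nh * var(psibar)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

# whiten an increment vector with the true tridiagonal covariance via the
# scalar LDL recursion (independent of the C++ path)
whitenTridiag <- function(x, dg, od) {
  k <- length(dg)
  d <- numeric(k); z <- numeric(k)
  d[1] <- dg[1]; z[1] <- x[1]
  if (k > 1) for (i in 2:k) {
    l <- od[i - 1] / d[i - 1]
    d[i] <- dg[i] - l * od[i - 1]
    z[i] <- x[i] - l * z[i - 1]
  }
  z / sqrt(d)
}

# a tiny fixed trajectory used by several files
tinyTrack <- function() {
  trajectory(c(0, 10, 20), rbind(c(0, 0), c(1, 0), c(1, 1)))
}
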