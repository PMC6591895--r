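#include <Rcpp.h>
using namespace Rcpp;

// Symmetric tridiagonal LDL^T factorization.
// d[i] are the pivots; l[i] the unit sub-diagonal multipliers.
// Returns false on a non-positive pivot (matrix not positive definite).
static bool ldl_factor(const NumericVector& dg, const NumericVector& od,
                       std::vector<double>& d, std::vector<double>& l) {
  const int k = dg.size();
  d.resize(k);
  l.resize(k > 0 ? k - 1 : 0);
  d[0] = dg[0];
  if (!(d[0] > 0.0) || !R_finite(d[0])) return false;
  for (int i = 1; i < k; ++i) {
    l[i - 1] = od[i - 1] / d[i - 1];
    d[i] = dg[i] - l[i - 1] * od[i - 1];
    if (!(d[i] > 0.0) || !R_finite(d[i])) return false;
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".tridiagLogdetC")]]
double tridiag_logdet(NumericVector dg, NumericVector od) {
  std::vector<double> d, l;
  if (!ldl_factor(dg, od, d, l)) return R_NegInf;
  double s = 0.0;
  for (double di : d) s += std::log(di);
  return s;
}

// Log-density of columns of X under N(0, Sigma) with Sigma the symmetric
// tridiagonal matrix (dg, od), summed over columns. The two coordinate axes
// of a trajectory share one factorization. Returns -Inf when Sigma is not
// positive definite so optimizers/samplers can reject.
//' @noRd
// [[Rcpp::export(name = ".tridiagLogpdfC")]]
double tridiag_logpdf(NumericVector dg, NumericVector od, NumericMatrix X) {
  const int k = dg.size();
  if (X.nrow() != k) stop("length of x does not match covariance order");
  std::vector<double> d, l;
  if (!ldl_factor(dg, od, d, l)) return R_NegInf;
  double logdet = 0.0;
  for (double di : d) logdet += std::log(di);
  const int nc = X.ncol();
  double quad = 0.0;
  std::vector<double> z(k);
  for (int c = 0; c < nc; ++c) {
    // forward solve L z = x, then quadratic form sum z_i^2 / d_i
    z[0] = X(0, c);
    for (int i = 1; i < k; ++i) z[i] = X(i, c) - l[i - 1] * z[i - 1];
    for (int i = 0; i < k; ++i) quad += z[i] * z[i] / d[i];
  }
  return -0.5 * (nc * k * std::log(2.0 * M_PI) + nc * logdet + quad);
}

// Solve Sigma y = x for symmetric tridiagonal Sigma via LDL^T.
//' @noRd
// [[Rcpp::export(name = ".tridiagSolveC")]]
NumericMatrix tridiag_solve(NumericVector dg, NumericVector od, NumericMatrix X) {
  const int k = dg.size();
  if (X.nrow() != k) stop("dimension mismatch");
  std::vector<double> d, l;
  if (!ldl_factor(dg, od, d, l))
    stop("matrix is not positive definite");
  NumericMatrix Y(k, X.ncol());
  for (int c = 0; c < X.ncol(); ++c) {
    // L z = x
    Y(0, c) = X(0, c);
    for (int i = 1; i < k; ++i) Y(i, c) = X(i, c) - l[i - 1] * Y(i - 1, c);
    // D w = z ; L^T y = w
    for (int i = 0; i < k; ++i) Y(i, c) /= d[i];
    for (int i = k - 2; i >= 0; --i) Y(i, c) -= l[i] * Y(i + 1, c);
  }
  return Y;
}
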