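#include <Rcpp.h>
using namespace Rcpp;

// Two-sided Fisher's exact p for a 2x2 table [[a, b], [c, d]] by summing
// hypergeometric point probabilities no larger than the observed one.
// Tables with at least one zero margin have p = 1 by convention.
static double fisher_p_one(double a, double b, double c, double d) {
  double m = a + b;        // row 1 total (white balls)
  double n = c + d;        // row 2 total (black balls)
  double k = a + c;        // column 1 total (draws)
  if (m + n <= 0 || k <= 0 || (b + d) <= 0 || m <= 0 || n <= 0)
    return 1.0;
  double lo = std::max(0.0, k - n);
  double hi = std::min(k, m);
  const double reltol = 1.0 + 1e-7;   // tie tolerance for discreteness
  double d0 = ::Rf_dhyper(a, m, n, k, 0);
  double p = 0.0;
  for (double x = lo; x <= hi; x += 1.0) {
    double dx = ::Rf_dhyper(x, m, n, k, 0);
    if (dx <= d0 * reltol) p += dx;
  }
  return std::min(p, 1.0);
}

//' Vectorised two-sided Fisher's exact test for 2x2 count tables
//'
//' @param a,b,c,d integer-valued vectors giving the cells of each table,
//'   laid out as \code{[[a, b], [c, d]]}; recycled to a common length is NOT
//'   performed, all four must have equal length.
//' @return numeric vector of two-sided p-values.
//' @noRd
// [[Rcpp::export(name = ".fisher2x2_cpp")]]
NumericVector fisher2x2_cpp(NumericVector a, NumericVector b,
                            NumericVector c, NumericVector d) {
  R_xlen_t n = a.size();
  if (b.size() != n || c.size() != n || d.size() != n)
    stop("all four count vectors must have the same length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double ai = a[i], bi = b[i], ci = c[i], di = d[i];
    if (NumericVector::is_na(ai) || NumericVector::is_na(bi) ||
        NumericVector::is_na(ci) || NumericVector::is_na(di)) {
      out[i] = NA_REAL;
      continue;
    }
    if (ai < 0 || bi < 0 || ci < 0 || di < 0)
      stop("counts must be non-negative");
    out[i] = fisher_p_one(ai, bi, ci, di);
  }
  return out;
}
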