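#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Two-locus interaction scan.
//
// For each SNP pair (i, j) fits y = b0 + b1*x1 + b2*x2 + b12*x1*x2 + e
// by OLS on pairwise complete cases and tests b12 with a two-sided
// t-test on n_used - 4 df.  The 4x4 normal equations are accumulated
// directly from the genotype/phenotype vectors; no design matrix is
// materialized.  Degenerate pairs (fewer than 5 complete cases,
// rank-deficient design, or zero residual/phenotype variance) yield NA
// statistics rather than aborting the scan.
//
// Returns a P x 6 matrix with columns beta12, se, t, df, p, n_used.
// [[Rcpp::export]]
NumericMatrix epi_scan_cpp(const NumericMatrix& G, const NumericVector& y,
                           const IntegerMatrix& pairs) {
  const int n = G.nrow();
  const int P = pairs.nrow();
  NumericMatrix out(P, 6);

  arma::mat A(4, 4);
  arma::vec b(4), beta(4);
  arma::mat Ainv(4, 4);

  for (int p = 0; p < P; ++p) {
    const int i = pairs(p, 0) - 1;
    const int j = pairs(p, 1) - 1;
    double s1 = 0, s2 = 0, s12 = 0, s11 = 0, s22 = 0;
    double s112 = 0, s122 = 0, s1122 = 0;
    double sy = 0, syy = 0, s1y = 0, s2y = 0, s12y = 0;
    int m = 0;
    for (int r = 0; r < n; ++r) {
      const double x1 = G(r, i), x2 = G(r, j), yv = y[r];
      if (ISNAN(x1) || ISNAN(x2) || ISNAN(yv)) continue;
      const double x12 = x1 * x2;
      ++m;
      s1 += x1; s2 += x2; s12 += x12;
      s11 += x1 * x1; s22 += x2 * x2;
      s112 += x1 * x12; s122 += x2 * x12; s1122 += x12 * x12;
      sy += yv; syy += yv * yv;
      s1y += x1 * yv; s2y += x2 * yv; s12y += x12 * yv;
    }
    double beta12 = NA_REAL, se = NA_REAL, tval = NA_REAL, pval = NA_REAL;
    double df = NA_REAL;
    if (m >= 5) {
      df = m - 4;
      const double ss_tot = syy - sy * sy / m;
      A(0,0) = m;    A(0,1) = s1;   A(0,2) = s2;   A(0,3) = s12;
      A(1,0) = s1;   A(1,1) = s11;  A(1,2) = s12;  A(1,3) = s112;
      A(2,0) = s2;   A(2,1) = s12;  A(2,2) = s22;  A(2,3) = s122;
      A(3,0) = s12;  A(3,1) = s112; A(3,2) = s122; A(3,3) = s1122;
      b[0] = sy; b[1] = s1y; b[2] = s2y; b[3] = s12y;
      const bool invertible = arma::inv(Ainv, A);
      const double rc = invertible ? arma::rcond(A) : 0.0;
      if (invertible && rc > 1e-12 && ss_tot > 0) {
        beta = Ainv * b;
        double rss = syy - arma::dot(beta, b);
        if (rss < 0) rss = 0;
        const double sigma2 = rss / df;
        if (sigma2 > 0 && Ainv(3,3) > 0) {
          beta12 = beta[3];
          se = std::sqrt(sigma2 * Ainv(3,3));
          tval = beta12 / se;
          pval = 2.0 * R::pt(-std::fabs(tval), df, 1, 0);
        }
      }
    }
    out(p, 0) = beta12;
    out(p, 1) = se;
    out(p, 2) = tval;
    out(p, 3) = df;
    out(p, 4) = pval;
    out(p, 5) = m;
  }
  colnames(out) = CharacterVector::create("beta12", "se", "t_stat", "df",
                                          "p_value", "n_used");
  return out;
}

// Minimum non-missing interaction p-value over a pair subset; 1.0 when
// the subset is empty or every pair is degenerate.
// [[Rcpp::export]]
double epi_scan_min_p_cpp(const NumericMatrix& G, const NumericVector& y,
                          const IntegerMatrix& pairs) {
  NumericMatrix res = epi_scan_cpp(G, y, pairs);
  double mn = 2.0;
  for (int p = 0; p < res.nrow(); ++p) {
    const double pv = res(p, 4);
    if (!ISNAN(pv) && pv < mn) mn = pv;
  }
  return (mn > 1.0) ? 1.0 : mn;
}
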