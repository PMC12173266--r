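#include <Rcpp.h>
using namespace Rcpp;

// Per-variant two-parameter logistic regression by Newton scoring:
// logit P(y = 1) = b0_j + b1_j * g_j, fit independently for every column j
// of the genotype matrix. Equivalent to glm(y ~ g_j, family = binomial)
// at convergence; standard errors from the inverse Fisher information.
//
// Because dosages take only the values 0/1/2, the likelihood depends on the
// data only through the six genotype-by-case counts, so each variant needs
// one O(n) counting pass and O(1) Newton iterations.
// [[Rcpp::export(name = ".logistic_scan_cpp")]]
List logistic_scan_cpp(const IntegerMatrix& g, const IntegerVector& y,
                       int max_iter = 50, double tol = 1e-10) {
  const int n = g.nrow(), m = g.ncol();
  NumericVector beta(m), se(m), intercept(m);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  const double b0_start = std::log(ybar / (1.0 - ybar));

  for (int j = 0; j < m; ++j) {
    double tot[3] = {0.0, 0.0, 0.0};    // individuals with dosage 0/1/2
    double cases[3] = {0.0, 0.0, 0.0};  // cases with dosage 0/1/2
    for (int i = 0; i < n; ++i) {
      const int x = g(i, j);
      tot[x] += 1.0;
      cases[x] += y[i];
    }
    double b0 = b0_start, b1 = 0.0;
    double i00 = 0.0, i01 = 0.0, i11 = 0.0;
    for (int iter = 0; iter < max_iter; ++iter) {
      double u0 = 0.0, u1 = 0.0;
      i00 = i01 = i11 = 0.0;
      for (int x = 0; x < 3; ++x) {
        if (tot[x] == 0.0) continue;
        const double mu = 1.0 / (1.0 + std::exp(-(b0 + b1 * x)));
        const double w = tot[x] * mu * (1.0 - mu);
        const double r = cases[x] - tot[x] * mu;
        u0 += r;
        u1 += x * r;
        i00 += w;
        i01 += x * w;
        i11 += x * x * w;
      }
      const double det = i00 * i11 - i01 * i01;
      const double d0 = (i11 * u0 - i01 * u1) / det;
      const double d1 = (i00 * u1 - i01 * u0) / det;
      b0 += d0;
      b1 += d1;
      if (std::max(std::fabs(d0), std::fabs(d1)) < tol) break;
    }
    // information refreshed at the converged estimate
    i00 = i01 = i11 = 0.0;
    for (int x = 0; x < 3; ++x) {
      if (tot[x] == 0.0) continue;
      const double mu = 1.0 / (1.0 + std::exp(-(b0 + b1 * x)));
      const double w = tot[x] * mu * (1.0 - mu);
      i00 += w;
      i01 += x * w;
      i11 += x * x * w;
    }
    const double det = i00 * i11 - i01 * i01;
    beta[j] = b1;
    se[j] = std::sqrt(i00 / det);
    intercept[j] = b0;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["intercept"] = intercept);
}
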