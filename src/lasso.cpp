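// L1-penalized logistic regression core: IRLS with cyclic coordinate
// descent and soft-thresholding on standardized columns. The objective is
// (1/n) * logistic log-loss + lambda * sum |b|; the intercept b0 is
// unpenalized. Outer convergence: max coefficient change across one full
// IRLS round below `tol`.
#include <Rcpp.h>
using namespace Rcpp;

static inline double soft_c(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".lasso_core_cpp")]]
List lasso_core_cpp(const NumericMatrix& Xs, const IntegerVector& y,
                    double lambda, double b0_init, const NumericVector& b_init,
                    int max_iter, double tol) {
  const int n = Xs.nrow(), p = Xs.ncol();
  double b0 = b0_init;
  std::vector<double> b(b_init.begin(), b_init.end());
  std::vector<double> w(n), r(n), b_old(p);
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    double b0_old = b0;
    std::copy(b.begin(), b.end(), b_old.begin());

    // working response at current estimates; r = z - b0 - Xs b
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) {
        if (b[j] != 0.0) e += Xs(i, j) * b[j];
      }
      if (e > 30.0) e = 30.0;
      if (e < -30.0) e = -30.0;
      double pr = 1.0 / (1.0 + std::exp(-e));
      double wi = pr * (1.0 - pr);
      if (wi < 1e-5) wi = 1e-5;
      w[i] = wi;
      r[i] = (y[i] - pr) / wi;
    }

    // coordinate descent on the weighted penalized least-squares problem:
    // full sweeps alternate with cheap sweeps over the active set only
    auto update_coord = [&](int j) -> double {
      double wj = 0.0, zj = 0.0;
      for (int i = 0; i < n; ++i) {
        const double x = Xs(i, j);
        wj += w[i] * x * x;
        zj += w[i] * x * (r[i] + x * b[j]);
      }
      const double bj = soft_c(zj / n, lambda) / (wj / n);
      const double diff = bj - b[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= Xs(i, j) * diff;
        b[j] = bj;
      }
      return std::fabs(diff);
    };
    auto update_intercept = [&]() -> double {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        num += w[i] * r[i];
        den += w[i];
      }
      const double d0 = num / den;
      if (d0 != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d0;
        b0 += d0;
      }
      return std::fabs(d0);
    };
    for (int cycle = 0; cycle < 10; ++cycle) {
      double delta = update_intercept();
      for (int j = 0; j < p; ++j) {
        const double d = update_coord(j);
        if (d > delta) delta = d;
      }
      if (delta < tol) break;
      for (int asweep = 0; asweep < 50; ++asweep) {
        double ad = update_intercept();
        for (int j = 0; j < p; ++j) {
          if (b[j] != 0.0) {
            const double d = update_coord(j);
            if (d > ad) ad = d;
          }
        }
        if (ad < tol) break;
      }
    }

    double round_delta = std::fabs(b0 - b0_old);
    for (int j = 0; j < p; ++j) {
      if (std::fabs(b[j] - b_old[j]) > round_delta) {
        round_delta = std::fabs(b[j] - b_old[j]);
      }
    }
    if (round_delta < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["b0"] = b0, _["b"] = NumericVector(b.begin(), b.end()),
                      _["converged"] = converged);
}
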