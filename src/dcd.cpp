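// Dual coordinate descent solvers for the linear models at the core of the
// package: epsilon-insensitive SVR (deconvolution) and hinge-loss SVM (the
// biomarker harness). Fixed sweep order keeps both fully deterministic.

#include <Rcpp.h>
using namespace Rcpp;

// min_w 0.5*||w||^2 + C * sum_i max(0, |x_i'w - y_i| - eps), no intercept.
// Dual variable beta_i in [-C, C] per row; w = X' beta maintained
// incrementally; each update is a box-clipped soft-threshold step.
// [[Rcpp::export(name = ".svr_dcd")]]
List svr_dcd(NumericMatrix X, NumericVector y, double C, double eps,
             double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> qii(n), beta(n, 0.0), w(p, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    double delta_max = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] == 0.0) continue;
      double g = -y[i];
      for (int j = 0; j < p; ++j) g += X(i, j) * w[j];
      double z = beta[i] - g / qii[i];
      double shrink = eps / qii[i];
      double b_new = 0.0;
      if (z > shrink) b_new = z - shrink;
      else if (z < -shrink) b_new = z + shrink;
      if (b_new > C) b_new = C;
      else if (b_new < -C) b_new = -C;
      double d = b_new - beta[i];
      if (d != 0.0) {
        beta[i] = b_new;
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        double step = std::fabs(d) * std::sqrt(qii[i]);
        if (step > delta_max) delta_max = step;
      }
    }
    if (delta_max < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["converged"] = converged);
}

// min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i * x_i'w), y in {-1, +1};
// the bias is expected as an augmented constant column of X.
// [[Rcpp::export(name = ".svm_dcd")]]
List svm_dcd(NumericMatrix X, NumericVector y, double C, double tol,
             int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> qii(n), alpha(n, 0.0), w(p, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    double delta_max = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] == 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += X(i, j) * w[j];
      g = y[i] * g - 1.0;
      double a_new = alpha[i] - g / qii[i];
      if (a_new < 0.0) a_new = 0.0;
      else if (a_new > C) a_new = C;
      double d = a_new - alpha[i];
      if (d != 0.0) {
        alpha[i] = a_new;
        for (int j = 0; j < p; ++j) w[j] += d * y[i] * X(i, j);
        if (std::fabs(d) > delta_max) delta_max = std::fabs(d);
      }
    }
    if (delta_max < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["converged"] = converged);
}
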