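#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// S(z, t) = sign(z) * max(|z| - t, 0)
static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One cyclic coordinate-descent sweep for (possibly weighted) least squares.
// r is the current residual; xx[j] = sum_i v_i x_ij^2 / n.  Returns the
// largest absolute coefficient change seen in the sweep.  Columns with
// active[j] == false are skipped.
static double sweep_gaussian(const NumericMatrix& X, std::vector<double>& r,
                             std::vector<double>& beta,
                             const std::vector<double>& xx,
                             const NumericVector& w, double lam, int n,
                             const std::vector<char>& use) {
  int p = X.ncol();
  double maxdiff = 0.0;
  for (int j = 0; j < p; ++j) {
    if (!use[j] || xx[j] <= 0.0) continue;
    const double* xj = &X(0, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * r[i];
    g /= n;
    double z = g + xx[j] * beta[j];
    double bj = soft(z, lam * w[j]) / xx[j];
    double d = bj - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bj;
      double ad = std::fabs(d);
      if (ad > maxdiff) maxdiff = ad;
    }
  }
  return maxdiff;
}

// Weighted-lasso path by cyclic coordinate descent with warm starts and an
// active-set refinement pass: iterate on the current active set until
// converged, then run one full sweep; stop when the full sweep moves nothing.
// Objective: (1/2n)||y - b0 - X beta||^2 + lam * sum_j w_j |beta_j|.
// [[Rcpp::export]]
List cd_gaussian_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& w, const NumericVector& lambdas,
                      double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s / n;
  }
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - ybar;
  std::vector<double> beta(p, 0.0);
  std::vector<char> all(p, 1), act(p, 0);

  NumericMatrix B(p, L);
  NumericVector b0(L);
  IntegerVector iters(L), nzero(L);
  LogicalVector converged(L);

  for (int l = 0; l < L; ++l) {
    double lam = lambdas[l];
    int it = 0;
    bool conv = false;
    while (it < max_iter) {
      // full sweep
      double d = sweep_gaussian(X, r, beta, xx, w, lam, n, all);
      ++it;
      if (d < tol) { conv = true; break; }
      // refine on active set
      for (int j = 0; j < p; ++j) act[j] = (beta[j] != 0.0);
      while (it < max_iter) {
        double da = sweep_gaussian(X, r, beta, xx, w, lam, n, act);
        ++it;
        if (da < tol) break;
      }
    }
    int nz = 0;
    for (int j = 0; j < p; ++j) {
      B(j, l) = beta[j];
      if (beta[j] != 0.0) ++nz;
    }
    b0[l] = ybar;
    iters[l] = it;
    nzero[l] = nz;
    converged[l] = conv;
  }
  return List::create(_["beta"] = B, _["intercept"] = b0,
                      _["iters"] = iters, _["nzero"] = nzero,
                      _["converged"] = converged);
}

static double sweep_wls(const NumericMatrix& X, std::vector<double>& r,
                        std::vector<double>& beta, double& b0,
                        const std::vector<double>& v, double sv,
                        const std::vector<double>& vx2,
                        const NumericVector& w, double lam, int n,
                        const std::vector<char>& use) {
  int p = X.ncol();
  double maxdiff = 0.0;
  for (int j = 0; j < p; ++j) {
    if (!use[j]) continue;
    double denom = vx2[j];
    if (denom <= 0.0) continue;
    const double* xj = &X(0, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += v[i] * xj[i] * r[i];
    g /= n;
    double z = g + denom * beta[j];
    double bj = soft(z, lam * w[j]) / denom;
    double d = bj - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bj;
      double ad = std::fabs(d);
      if (ad > maxdiff) maxdiff = ad;
    }
  }
  // unpenalized intercept
  double d0 = 0.0;
  for (int i = 0; i < n; ++i) d0 += v[i] * r[i];
  d0 /= sv;
  if (d0 != 0.0) {
    for (int i = 0; i < n; ++i) r[i] -= d0;
    b0 += d0;
    double ad = std::fabs(d0);
    if (ad > maxdiff) maxdiff = ad;
  }
  return maxdiff;
}

// Binomial weighted-lasso path: IRLS outer loop, coordinate descent on the
// penalized weighted least-squares subproblem inside.  Working weights are
// floored at 1e-5 and probabilities clipped to [1e-10, 1 - 1e-10].
// [[Rcpp::export]]
List cd_binomial_path(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& w, const NumericVector& lambdas,
                      double tol, int max_iter) {
  const double PMIN = 1e-10, VMIN = 1e-5;
  const int MAX_OUTER = 50;  // IRLS relinearizations per lambda
  int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar < PMIN) ybar = PMIN;
  if (ybar > 1 - PMIN) ybar = 1 - PMIN;

  std::vector<double> beta(p, 0.0);
  double b0 = std::log(ybar / (1.0 - ybar));
  double null_dev = 0.0;
  for (int i = 0; i < n; ++i)
    null_dev += -2.0 * (y[i] * std::log(ybar) + (1 - y[i]) * std::log(1 - ybar));
  std::vector<double> eta(n), prob(n), v(n), r(n);
  std::vector<char> all(p, 1), act(p, 0);

  NumericMatrix B(p, L);
  NumericVector b0s(L);
  IntegerVector iters(L), nzero(L);
  LogicalVector converged(L);

  for (int l = 0; l < L; ++l) {
    double lam = lambdas[l];
    bool conv = false;
    int outer = 0, inner_total = 0;
    while (outer < MAX_OUTER) {
      ++outer;
      // IRLS linearization at current (b0, beta)
      double sv = 0.0, dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
        double pi = 1.0 / (1.0 + std::exp(-e));
        if (pi < PMIN) pi = PMIN;
        if (pi > 1 - PMIN) pi = 1 - PMIN;
        prob[i] = pi;
        dev += -2.0 * (y[i] * std::log(pi) + (1 - y[i]) * std::log(1 - pi));
        double vi = pi * (1.0 - pi);
        if (vi < VMIN) vi = VMIN;
        v[i] = vi;
        sv += vi;
        r[i] = (y[i] - pi) / vi;  // working residual z - eta
      }
      // saturation guard: the fit explains essentially all the deviance
      if (dev < 0.01 * null_dev) { conv = true; break; }
      std::vector<double> vx2(p);
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += v[i] * X(i, j) * X(i, j);
        vx2[j] = s / n;
      }
      // solve penalized WLS at this linearization
      double b0_in = b0;
      std::vector<double> beta_in(beta);
      int inner = 0;
      int budget = max_iter - inner_total;  // max_iter caps total sweeps per lambda
      while (inner < budget) {
        double d = sweep_wls(X, r, beta, b0, v, sv, vx2, w, lam, n, all);
        ++inner;
        if (d < tol) break;
        for (int j = 0; j < p; ++j) act[j] = (beta[j] != 0.0);
        while (inner < budget) {
          double da = sweep_wls(X, r, beta, b0, v, sv, vx2, w, lam, n, act);
          ++inner;
          if (da < tol) break;
        }
      }
      inner_total += inner;
      double dmax = std::fabs(b0 - b0_in);
      for (int j = 0; j < p; ++j) {
        double d = std::fabs(beta[j] - beta_in[j]);
        if (d > dmax) dmax = d;
      }
      if (dmax < tol * 10) { conv = true; break; }
      if (inner_total >= max_iter) break;
    }
    int nz = 0;
    for (int j = 0; j < p; ++j) {
      B(j, l) = beta[j];
      if (beta[j] != 0.0) ++nz;
    }
    b0s[l] = b0;
    iters[l] = inner_total;
    nzero[l] = nz;
    converged[l] = conv;
  }
  return List::create(_["beta"] = B, _["intercept"] = b0s,
                      _["iters"] = iters, _["nzero"] = nzero,
                      _["converged"] = converged);
}
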