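#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the L1-penalized squared-error objective
//   L(beta) = || y - b0 - X beta ||_2^2 + lambda * || beta ||_1
// with an unpenalized intercept b0. X is used as supplied; standardization
// is the caller's responsibility. The coordinate update for column j is
//   beta_j <- S(x_j' r_j, lambda / 2) / (x_j' x_j)
// where r_j is the partial residual including column j's contribution and
// S is the soft-threshold operator (the factor 1/2 comes from the squared
// error carrying no 1/2 in this convention).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double update_coord(const double* Xp, int n, int j,
                                  double lambda, std::vector<double>& beta,
                                  std::vector<double>& r,
                                  const std::vector<double>& xtx) {
  if (xtx[j] <= 0.0) { beta[j] = 0.0; return 0.0; }
  const double* xj = Xp + (size_t)j * n;
  double zj = 0.0;
  for (int i = 0; i < n; i++) zj += xj[i] * r[i];
  zj += xtx[j] * beta[j];
  double bnew = soft(zj, lambda / 2.0) / xtx[j];
  double delta = bnew - beta[j];
  if (delta != 0.0) {
    for (int i = 0; i < n; i++) r[i] -= xj[i] * delta;
    beta[j] = bnew;
  }
  return std::fabs(delta);
}

static inline double update_intercept(int n, double& b0,
                                      std::vector<double>& r) {
  double rbar = 0.0;
  for (int i = 0; i < n; i++) rbar += r[i];
  rbar /= n;
  if (rbar != 0.0) {
    b0 += rbar;
    for (int i = 0; i < n; i++) r[i] -= rbar;
  }
  return std::fabs(rbar);
}

// Full sweeps alternate with iteration restricted to the current active set
// (nonzero coefficients), the standard acceleration for pathwise fits.
static void cd_solve(const NumericMatrix& X, const NumericVector& y,
                     double lambda, double& b0, std::vector<double>& beta,
                     std::vector<double>& r, const std::vector<double>& xtx,
                     double tol, int maxit) {
  int n = X.nrow(), p = X.ncol();
  const double* Xp = X.begin();
  int used = 0;
  while (used < maxit) {
    // full sweep over all coordinates
    double maxdelta = update_intercept(n, b0, r);
    for (int j = 0; j < p; j++)
      maxdelta = std::max(maxdelta, update_coord(Xp, n, j, lambda, beta, r,
                                                 xtx));
    used++;
    if (maxdelta < tol) break;
    // active-set iterations
    std::vector<int> active;
    for (int j = 0; j < p; j++) if (beta[j] != 0.0) active.push_back(j);
    while (used < maxit) {
      double md = update_intercept(n, b0, r);
      for (size_t k = 0; k < active.size(); k++)
        md = std::max(md, update_coord(Xp, n, active[k], lambda, beta, r,
                                       xtx));
      used++;
      if (md < tol) break;
    }
  }
}

// [[Rcpp::export]]
List lasso_cd(NumericMatrix X, NumericVector y, double lambda,
              double tol = 1e-10, int maxit = 100000) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p, 0.0), r(n), xtx(p, 0.0);
  double b0 = 0.0;
  for (int i = 0; i < n; i++) r[i] = y[i];
  for (int j = 0; j < p; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  cd_solve(X, y, lambda, b0, beta, r, xtx, tol, maxit);
  return List::create(_["intercept"] = b0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()));
}

// Pathwise fit with warm starts; lambdas must be sorted decreasing.
// [[Rcpp::export]]
List lasso_path_cd(NumericMatrix X, NumericVector y, NumericVector lambdas,
                   double tol = 1e-9, int maxit = 100000) {
  int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  std::vector<double> beta(p, 0.0), r(n), xtx(p, 0.0);
  double b0 = 0.0;
  for (int i = 0; i < n; i++) r[i] = y[i];
  for (int j = 0; j < p; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  NumericMatrix B(p, L);
  NumericVector B0(L);
  for (int l = 0; l < L; l++) {
    cd_solve(X, y, lambdas[l], b0, beta, r, xtx, tol, maxit);
    for (int j = 0; j < p; j++) B(j, l) = beta[j];
    B0[l] = b0;
  }
  return List::create(_["intercept"] = B0, _["beta"] = B);
}
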