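// L1-penalized logistic regression by proximal Newton / coordinate descent.
// Objective: (1/n) * sum_i -[y_i*eta_i - log(1+exp(eta_i))] + lambda * sum_j pen_j*|beta_j|
// Intercept always unpenalized. pen_j is a per-coefficient penalty multiplier
// (0 exempts a coefficient, e.g. an autoregressive path).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double WEIGHT_FLOOR = 1e-5;
static const double PROB_EPS = 1e-12;

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One penalized fit at a single lambda, warm-started from (b0, beta).
// Returns true on convergence; iters reports outer Newton iterations used.
static bool cd_fit(const NumericMatrix& X, const NumericVector& y,
                   double lambda, const NumericVector& pen,
                   double tol, int maxit,
                   double& b0, std::vector<double>& beta, int& iters) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(n), z(n), eta(n), xbar(p), c(p), gdiag(p),
      G(p * p), beta_old(p);
  std::vector<char> have_col(p);
  iters = 0;

  // penalized objective: (1/n) sum[log(1+e^eta) - y*eta] + lambda*sum pen|b|
  auto update_eta = [&](void) {
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      double bj = beta[j];
      if (bj != 0.0) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
      }
    }
  };
  auto objective = [&](void) {
    double nll = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      // stable log(1 + exp(e))
      double l1pe = (e > 0) ? e + std::log1p(std::exp(-e))
                            : std::log1p(std::exp(e));
      nll += l1pe - y[i] * e;
    }
    double penv = 0.0;
    for (int j = 0; j < p; ++j) penv += pen[j] * std::fabs(beta[j]);
    return nll / n + lambda * penv;
  };

  for (int outer = 0; outer < maxit; ++outer) {
    ++iters;
    update_eta();
    double obj0 = objective();
    double b0_old = b0;
    for (int j = 0; j < p; ++j) beta_old[j] = beta[j];
    // quadratic approximation at the current estimate
    double sw = 0.0, swz = 0.0;
    for (int i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta[i]));
      double wi = mu * (1.0 - mu);
      if (wi < WEIGHT_FLOOR) wi = WEIGHT_FLOOR;
      w[i] = wi;
      z[i] = eta[i] + (y[i] - mu) / wi;   // working response
      sw += wi;
      swz += wi * z[i];
    }
    double zbar = swz / sw;
    // weighted-centered gradient and curvature: the intercept is solved
    // exactly by centering, so the inner problem is p-dimensional; full
    // Gram columns are formed lazily, only for coordinates that activate
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double s = 0.0, cj = 0.0, g = 0.0;
      for (int i = 0; i < n; ++i) {
        double xw = w[i] * xj[i];
        s += xw;
        cj += xw * (z[i] - zbar);
        g += xw * xj[i];
      }
      xbar[j] = s / sw;
      c[j] = cj / n;
      gdiag[j] = (g - sw * xbar[j] * xbar[j]) / n;
      have_col[j] = 0;
    }
    double outer_delta = 0.0;
    for (int inner = 0; inner < 10000; ++inner) {
      double inner_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double gjj = gdiag[j];
        if (gjj <= 0.0) continue;   // constant column after centering
        double grad = c[j];
        for (int k = 0; k < p; ++k) {
          if (k == j || beta[k] == 0.0) continue;
          if (!have_col[k]) {   // materialize Gram column k on demand
            const double* xk = &X(0, k);
            for (int jj = 0; jj < p; ++jj) {
              const double* xjj = &X(0, jj);
              double g = 0.0;
              for (int i = 0; i < n; ++i) g += w[i] * xk[i] * xjj[i];
              G[k * p + jj] = (g - sw * xbar[k] * xbar[jj]) / n;
            }
            have_col[k] = 1;
          }
          grad -= G[k * p + j] * beta[k];
        }
        double bj_new = soft_threshold(grad, lambda * pen[j]) / gjj;
        double d = bj_new - beta[j];
        if (d != 0.0) {
          beta[j] = bj_new;
          inner_delta = std::max(inner_delta, std::fabs(d));
        }
      }
      outer_delta = std::max(outer_delta, inner_delta);
      if (inner_delta < tol) break;
    }
    b0 = zbar;
    for (int j = 0; j < p; ++j) b0 -= xbar[j] * beta[j];
    // step halving keeps the penalized objective monotone: the quadratic
    // model can overshoot when weights are floored near mu = 0 or 1
    update_eta();
    for (int h = 0; h < 30 && objective() > obj0 + 1e-12; ++h) {
      b0 = 0.5 * (b0 + b0_old);
      for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + beta_old[j]);
      update_eta();
    }
    outer_delta = std::fabs(b0 - b0_old);
    for (int j = 0; j < p; ++j)
      outer_delta = std::max(outer_delta, std::fabs(beta[j] - beta_old[j]));
    if (outer_delta < tol) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cd_logistic_cpp(NumericMatrix X, NumericVector y, double lambda,
                     NumericVector pen, double tol, int maxit,
                     double b0_init, NumericVector beta_init) {
  const int p = X.ncol();
  double b0 = b0_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  int iters = 0;
  bool ok = cd_fit(X, y, lambda, pen, tol, maxit, b0, beta, iters);
  return List::create(_["intercept"] = b0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iterations"] = iters,
                      _["converged"] = ok,
                      _["p"] = p);
}

// Warm-started path over a decreasing lambda sequence.
// [[Rcpp::export]]
List cd_logistic_path_cpp(NumericMatrix X, NumericVector y,
                          NumericVector lambdas, NumericVector pen,
                          double tol, int maxit) {
  const int p = X.ncol(), nl = lambdas.size(), n = X.nrow();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> beta(p, 0.0);
  NumericMatrix coefs(p, nl);
  NumericVector intercepts(nl);
  LogicalVector conv(nl);
  int iters;
  for (int l = 0; l < nl; ++l) {
    conv[l] = cd_fit(X, y, lambdas[l], pen, tol, maxit, b0, beta, iters);
    intercepts[l] = b0;
    for (int j = 0; j < p; ++j) coefs(j, l) = beta[j];
  }
  return List::create(_["intercepts"] = intercepts, _["coefs"] = coefs,
                      _["converged"] = conv);
}

// K-fold CV: mean per-fold out-of-fold binomial deviance for each lambda.
// foldid is 1-based. Returns nlambda x K matrix.
// [[Rcpp::export]]
NumericMatrix cv_deviance_cpp(NumericMatrix X, NumericVector y,
                              IntegerVector foldid, int nfolds,
                              NumericVector lambdas, NumericVector pen,
                              double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix dev(nl, nfolds);
  for (int k = 1; k <= nfolds; ++k) {
    int ntr = 0, nte = 0;
    for (int i = 0; i < n; ++i) (foldid[i] == k) ? ++nte : ++ntr;
    NumericMatrix Xtr(ntr, p), Xte(nte, p);
    NumericVector ytr(ntr), yte(nte);
    int a = 0, b = 0;
    for (int i = 0; i < n; ++i) {
      if (foldid[i] == k) {
        for (int j = 0; j < p; ++j) Xte(b, j) = X(i, j);
        yte[b++] = y[i];
      } else {
        for (int j = 0; j < p; ++j) Xtr(a, j) = X(i, j);
        ytr[a++] = y[i];
      }
    }
    double ybar = 0.0;
    for (int i = 0; i < ntr; ++i) ybar += ytr[i];
    ybar /= ntr;
    double b0 = std::log(ybar / (1.0 - ybar));
    std::vector<double> beta(p, 0.0);
    int iters;
    for (int l = 0; l < nl; ++l) {
      cd_fit(Xtr, ytr, lambdas[l], pen, tol, maxit, b0, beta, iters);
      double d = 0.0;
      for (int i = 0; i < nte; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) e += Xte(i, j) * beta[j];
        double mu = 1.0 / (1.0 + std::exp(-e));
        if (mu < PROB_EPS) mu = PROB_EPS;
        if (mu > 1.0 - PROB_EPS) mu = 1.0 - PROB_EPS;
        d += yte[i] * std::log(mu) + (1.0 - yte[i]) * std::log(1.0 - mu);
      }
      dev(l, k - 1) = -2.0 * d / nte;
    }
  }
  return dev;
}
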