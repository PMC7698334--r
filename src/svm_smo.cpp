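#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVM dual with a linear kernel,
// maximal-violating-pair working-set selection (no shrinking; problems here
// have at most a few dozen samples).
//
// Dual: min 1/2 a' Q a - sum(a),  0 <= a_i <= C,  sum(a_i y_i) = 0,
// with Q_ij = y_i y_j <x_i, x_j>.
//
// Decision convention: f(x) = <w, x> + b, f > 0 => y = +1.

struct SmoFit {
  std::vector<double> w;
  double b;
  std::vector<double> alpha;
  int iterations;
};

// X row-major (n rows of p doubles), y in {+1, -1}
static SmoFit smo_core(const std::vector<double>& X, int n, int p,
                       const std::vector<double>& y, double cost,
                       double eps = 1e-8, int max_iter = 200000) {
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &X[(size_t)i * p];
    for (int j = 0; j <= i; ++j) {
      const double* xj = &X[(size_t)j * p];
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += xi[k] * xj[k];
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = (Q a)_i - 1
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < cost) : (alpha[t] > 0);
      bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < cost);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    // two-variable analytic step along (da_i, da_j) = (y_i, -y_j) * t
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta <= 0) eta = 1e-12;
    double tstar = (gmax - gmin) / eta;

    double tmax = (y[i] > 0) ? (cost - alpha[i]) : alpha[i];
    double tmax_j = (y[j] > 0) ? alpha[j] : (cost - alpha[j]);
    if (tmax_j < tmax) tmax = tmax_j;
    if (tstar > tmax) tstar = tmax;

    double dai = y[i] * tstar, daj = -y[j] * tstar;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai +
                      y[j] * K[(size_t)t * n + j] * daj);
    }
  }

  // bias from the KKT conditions: for free SVs, b = y_i - f_i = -y_i G_i;
  // I_up members give lower bounds on b, I_low members upper bounds
  double bsum = 0.0;
  int nfree = 0;
  double lb = -1e300, ub = 1e300;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0) ? (alpha[t] < cost) : (alpha[t] > 0);
    bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < cost);
    if (alpha[t] > 1e-12 && alpha[t] < cost - 1e-12) { bsum += v; ++nfree; }
    if (up && v > lb) lb = v;
    if (lo && v < ub) ub = v;
  }
  SmoFit fit;
  fit.b = nfree > 0 ? bsum / nfree : (lb + ub) / 2.0;
  fit.w.assign(p, 0.0);
  for (int t = 0; t < n; ++t) {
    double c = alpha[t] * y[t];
    if (c == 0.0) continue;
    const double* xt = &X[(size_t)t * p];
    for (int k = 0; k < p; ++k) fit.w[k] += c * xt[k];
  }
  fit.alpha = alpha;
  fit.iterations = iter;
  return fit;
}

// [[Rcpp::export(name = ".svm_smo")]]
List svm_smo(NumericMatrix X, NumericVector y, double cost,
             double eps = 1e-8, int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  std::vector<double> Xr((size_t)n * p), yv(y.begin(), y.end());
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) Xr[(size_t)i * p + k] = X(i, k);
  SmoFit fit = smo_core(Xr, n, p, yv, cost, eps, max_iter);
  return List::create(_["w"] = NumericVector(fit.w.begin(), fit.w.end()),
                      _["b"] = fit.b,
                      _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["iterations"] = fit.iterations);
}

// Welch t ranking of all columns of X restricted to rows `rows`;
// zero-variance denominators get |t| = 0 (ranked last), ties break toward
// the lower column index. Returns 0-based column order.
static std::vector<int> rank_ttest(const NumericMatrix& X,
                                   const std::vector<int>& rows,
                                   const NumericVector& y) {
  const int p = X.ncol();
  int n1 = 0, n2 = 0;
  for (int r : rows) (y[r] > 0) ? ++n1 : ++n2;
  std::vector<double> abst(p);
  for (int c = 0; c < p; ++c) {
    double s1 = 0, q1 = 0, s2 = 0, q2 = 0;
    for (int r : rows) {
      double v = X(r, c);
      if (y[r] > 0) { s1 += v; q1 += v * v; } else { s2 += v; q2 += v * v; }
    }
    double m1 = s1 / n1, m2 = s2 / n2;
    double v1 = std::max(q1 - n1 * m1 * m1, 0.0) / (n1 - 1);
    double v2 = std::max(q2 - n2 * m2 * m2, 0.0) / (n2 - 1);
    double den = std::sqrt(v1 / n1 + v2 / n2);
    abst[c] = den > 0 ? std::fabs((m1 - m2) / den) : 0.0;
  }
  std::vector<int> ord(p);
  for (int c = 0; c < p; ++c) ord[c] = c;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return abst[a] > abst[b];
  });
  return ord;
}

// Standardize rows/cols subset of X by its own mean/sd, fit the SVM, and
// return raw-scale weights: decision(x) = sum_j x[cols[j]] * w_raw[j] + b_raw.
static void fit_fold(const NumericMatrix& X, const std::vector<int>& rows,
                     const std::vector<int>& cols, const NumericVector& y,
                     double cost, bool standardize,
                     std::vector<double>& w_raw, double& b_raw,
                     std::vector<double>* mu_out = nullptr,
                     std::vector<double>* sg_out = nullptr,
                     std::vector<double>* w_std = nullptr,
                     double* b_std = nullptr,
                     std::vector<double>* alpha_out = nullptr) {
  const int n = (int)rows.size(), k = (int)cols.size();
  std::vector<double> mu(k, 0.0), sg(k, 1.0);
  if (standardize) {
    for (int j = 0; j < k; ++j) {
      double s = 0, q = 0;
      for (int r : rows) { double v = X(r, cols[j]); s += v; q += v * v; }
      mu[j] = s / n;
      double var = std::max(q - n * mu[j] * mu[j], 0.0) / (n - 1);
      sg[j] = std::sqrt(var);
      if (sg[j] < 1e-12) sg[j] = 1.0;
    }
  }
  std::vector<double> Xs((size_t)n * k), yv(n);
  for (int i = 0; i < n; ++i) {
    yv[i] = y[rows[i]];
    for (int j = 0; j < k; ++j)
      Xs[(size_t)i * k + j] = (X(rows[i], cols[j]) - mu[j]) / sg[j];
  }
  SmoFit fit = smo_core(Xs, n, k, yv, cost);
  w_raw.assign(k, 0.0);
  b_raw = fit.b;
  for (int j = 0; j < k; ++j) {
    w_raw[j] = fit.w[j] / sg[j];
    b_raw -= mu[j] * w_raw[j];
  }
  if (mu_out) *mu_out = mu;
  if (sg_out) *sg_out = sg;
  if (w_std) *w_std = fit.w;
  if (b_std) *b_std = fit.b;
  if (alpha_out) *alpha_out = fit.alpha;
}

static void check_classes(const std::vector<int>& rows, const NumericVector& y) {
  int n1 = 0, n2 = 0;
  for (int r : rows) (y[r] > 0) ? ++n1 : ++n2;
  if (n1 < 2 || n2 < 2)
    stop("inner leave-one-out needs at least 2 samples per class after holding one out.");
}

// Inner leave-one-out over rows `rows` of X: for each candidate k in
// 1..k_max, re-rank features on every inner-training subset, train on the
// top k, predict the held-out inner sample. Returns per-k accuracy.
static std::vector<double> inner_accuracy(const NumericMatrix& X,
                                          const std::vector<int>& rows,
                                          const NumericVector& y, double cost,
                                          int k_max, bool standardize) {
  const int n = (int)rows.size();
  const int km = std::min(k_max, (int)X.ncol());
  std::vector<int> correct(km, 0);
  std::vector<double> w_raw;
  double b_raw;
  for (int i = 0; i < n; ++i) {
    std::vector<int> tr;
    tr.reserve(n - 1);
    for (int t = 0; t < n; ++t)
      if (t != i) tr.push_back(rows[t]);
    check_classes(tr, y);
    std::vector<int> ord = rank_ttest(X, tr, y);
    for (int k = 1; k <= km; ++k) {
      std::vector<int> cols(ord.begin(), ord.begin() + k);
      fit_fold(X, tr, cols, y, cost, standardize, w_raw, b_raw);
      double d = b_raw;
      for (int j = 0; j < k; ++j) d += X(rows[i], cols[j]) * w_raw[j];
      if ((d >= 0) == (y[rows[i]] > 0)) ++correct[k - 1];
    }
  }
  std::vector<double> acc(km);
  for (int k = 0; k < km; ++k) acc[k] = (double)correct[k] / n;
  return acc;
}

static int pick_k(const std::vector<double>& acc, bool first_local_max) {
  const int km = (int)acc.size();
  if (first_local_max) {
    for (int k = 0; k + 1 < km; ++k)
      if (acc[k + 1] <= acc[k]) return k + 1;
    return km;
  }
  int best = 0;
  for (int k = 1; k < km; ++k)
    if (acc[k] > acc[best]) best = k; // strict: smallest k wins ties
  return best + 1;
}

// [[Rcpp::export(name = ".choose_k_cpp")]]
List choose_k_cpp(NumericMatrix X, NumericVector y, double cost, int k_max,
                  bool standardize, bool first_local_max) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<double> acc = inner_accuracy(X, rows, y, cost, k_max, standardize);
  return List::create(_["k"] = pick_k(acc, first_local_max),
                      _["inner_accuracy"] = NumericVector(acc.begin(), acc.end()));
}

// One outer fold of the nested leave-one-out CV: hold out row s (1-based),
// choose k by the inner loop, rank on the full remainder, train on the top
// k, predict the held-out sample.
// [[Rcpp::export(name = ".nested_fold_cpp")]]
List nested_fold_cpp(NumericMatrix X, NumericVector y, int s, double cost,
                     int k_max, bool standardize, bool first_local_max) {
  const int n = X.nrow();
  if (s < 1 || s > n) stop("holdout index out of range");
  std::vector<int> tr;
  tr.reserve(n - 1);
  for (int t = 0; t < n; ++t)
    if (t != s - 1) tr.push_back(t);

  std::vector<double> acc = inner_accuracy(X, tr, y, cost, k_max, standardize);
  int k = pick_k(acc, first_local_max);

  std::vector<int> ord = rank_ttest(X, tr, y);
  std::vector<int> cols(ord.begin(), ord.begin() + k);
  std::vector<double> w_raw, mu, sg, w_std, alpha;
  double b_raw, b_std;
  fit_fold(X, tr, cols, y, cost, standardize, w_raw, b_raw, &mu, &sg,
           &w_std, &b_std, &alpha);
  double d = b_raw;
  for (int j = 0; j < k; ++j) d += X(s - 1, cols[j]) * w_raw[j];

  IntegerVector selected(cols.begin(), cols.end());
  return List::create(
      _["k"] = k, _["selected"] = selected + 1,
      _["w"] = NumericVector(w_std.begin(), w_std.end()), _["b"] = b_std,
      _["w_raw"] = NumericVector(w_raw.begin(), w_raw.end()), _["b_raw"] = b_raw,
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sigma"] = NumericVector(sg.begin(), sg.end()),
      _["inner_accuracy"] = NumericVector(acc.begin(), acc.end()),
      _["decision"] = d, _["predicted_pos"] = (d >= 0));
}
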