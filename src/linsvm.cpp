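#include <Rcpp.h>
#include <vector>
#include <cmath>

// Linear C-SVC solved by SMO on the dual (maximal-violating-pair working set
// selection, as in standard SVM libraries). Sample counts here are tiny
// (tens), so the Gram matrix is precomputed densely per fold. This compiled
// path exists because the wrapper selection and permutation tests evaluate
// the LOOCV criterion millions of times.

namespace {

const double TAU = 1e-12;

// Solve min 1/2 a'Qa - e'a  s.t. 0 <= a_i <= C, sum y_i a_i = 0,
// Q_ij = y_i y_j K_ij. Returns alpha and rho; decision f(x) = sum a_i y_i K(x_i,x) - rho.
void solve_smo(const std::vector<double>& K, const std::vector<int>& y,
               int n, double C, std::vector<double>& alpha, double& rho) {
  std::vector<double> G(n, -1.0);  // gradient of dual objective
  alpha.assign(n, 0.0);
  const double eps = 1e-3;  // libsvm default working-set tolerance
  const int max_iter = 200000;

  for (int iter = 0; iter < max_iter; ++iter) {
    // working set: i = argmax_{I_up} -y G, j = argmin_{I_low} -y G
    int i = -1, j = -1;
    double Gmax = -1e300, Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    // curvature along the feasible direction; equals Q_ii+Q_jj+2Q_ij for
    // opposite labels and Q_ii+Q_jj-2Q_ij for equal labels, both reduce to
    // ||z_i - z_j||^2 for the linear kernel
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = TAU;
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * y[i] * K[(size_t)t * n + i] * dai
            + y[t] * y[j] * K[(size_t)t * n + j] * daj;
    }
  }

  // rho: average of y*G over free support vectors, else midpoint of KKT bounds
  double ub = 1e300, lb = -1e300, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
}

// column means / sds of the training rows; sd floored at tiny -> 1 (constant column)
void train_scale(const Rcpp::NumericMatrix& X, const std::vector<int>& rows,
                 std::vector<double>& mu, std::vector<double>& sd) {
  int p = X.ncol(), m = (int)rows.size();
  mu.assign(p, 0.0); sd.assign(p, 1.0);
  for (int c = 0; c < p; ++c) {
    double s = 0;
    for (int r = 0; r < m; ++r) s += X(rows[r], c);
    mu[c] = s / m;
    double v = 0;
    for (int r = 0; r < m; ++r) { double d = X(rows[r], c) - mu[c]; v += d * d; }
    v = m > 1 ? v / (m - 1) : 0.0;
    sd[c] = (v > 1e-24) ? std::sqrt(v) : 1.0;
  }
}

// fit on rows `tr` of X (standardized if asked), predict the given test rows
void fit_predict(const Rcpp::NumericMatrix& X, const std::vector<int>& ytr,
                 const std::vector<int>& tr, const std::vector<int>& te,
                 double C, bool standardize, std::vector<int>& pred) {
  int p = X.ncol(), m = (int)tr.size();
  // single-class training fold: constant prediction
  bool all_same = true;
  for (int r = 1; r < m; ++r) if (ytr[r] != ytr[0]) { all_same = false; break; }
  if (all_same) { pred.assign(te.size(), ytr[0]); return; }

  std::vector<double> mu(p, 0.0), sd(p, 1.0);
  if (standardize) train_scale(X, tr, mu, sd);

  std::vector<double> Z((size_t)m * p);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < p; ++c)
      Z[(size_t)r * p + c] = (X(tr[r], c) - mu[c]) / sd[c];

  std::vector<double> K((size_t)m * m);
  for (int a = 0; a < m; ++a)
    for (int b = a; b < m; ++b) {
      double s = 0;
      for (int c = 0; c < p; ++c) s += Z[(size_t)a * p + c] * Z[(size_t)b * p + c];
      K[(size_t)a * m + b] = s; K[(size_t)b * m + a] = s;
    }

  std::vector<double> alpha;
  double rho;
  solve_smo(K, ytr, m, C, alpha, rho);

  // w = sum alpha_i y_i z_i
  std::vector<double> w(p, 0.0);
  for (int a = 0; a < m; ++a) {
    double ay = alpha[a] * ytr[a];
    if (ay != 0.0)
      for (int c = 0; c < p; ++c) w[c] += ay * Z[(size_t)a * p + c];
  }

  pred.resize(te.size());
  for (size_t t = 0; t < te.size(); ++t) {
    double f = -rho;
    for (int c = 0; c < p; ++c) f += w[c] * (X(te[t], c) - mu[c]) / sd[c];
    pred[t] = (f >= 0) ? 1 : -1;
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector svm_loocv_cpp(Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                                  double C, bool standardize) {
  int n = X.nrow();
  if (y.size() != n) Rcpp::stop("length(y) must equal nrow(X)");
  Rcpp::IntegerVector out(n);
  std::vector<int> tr(n - 1), ytr(n - 1), te(1), pred;
  for (int hold = 0; hold < n; ++hold) {
    int k = 0;
    for (int r = 0; r < n; ++r) if (r != hold) { tr[k] = r; ytr[k] = y[r]; ++k; }
    te[0] = hold;
    fit_predict(X, ytr, tr, te, C, standardize, pred);
    out[hold] = pred[0];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector svm_fit_predict_cpp(Rcpp::NumericMatrix Xtr, Rcpp::IntegerVector ytr,
                                        Rcpp::NumericMatrix Xte, double C, bool standardize) {
  int n = Xtr.nrow(), p = Xtr.ncol();
  if (Xte.ncol() != p) Rcpp::stop("column mismatch between training and test data");
  // stack train and test so fit_predict can index one matrix
  Rcpp::NumericMatrix X(n + Xte.nrow(), p);
  for (int r = 0; r < n; ++r) for (int c = 0; c < p; ++c) X(r, c) = Xtr(r, c);
  for (int r = 0; r < Xte.nrow(); ++r) for (int c = 0; c < p; ++c) X(n + r, c) = Xte(r, c);
  std::vector<int> tr(n), yv(n), te(Xte.nrow()), pred;
  for (int r = 0; r < n; ++r) { tr[r] = r; yv[r] = ytr[r]; }
  for (int r = 0; r < Xte.nrow(); ++r) te[r] = n + r;
  fit_predict(X, yv, tr, te, C, standardize, pred);
  return Rcpp::IntegerVector(pred.begin(), pred.end());
}
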