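#include <Rcpp.h>
using namespace Rcpp;

// Dual C-SVM solved by sequential minimal optimisation with deterministic
// working-set selection (first violator scan, partner = argmax |E_i - E_j|).
// Small dense problems only: the per-term training sets here are a few
// hundred rows, so the full kernel matrix is kept in memory.

namespace {

struct SmoFit {
  std::vector<double> alpha;
  double b;
  int iter;
};

SmoFit smo_solve(const NumericMatrix &K, const std::vector<int> &y, double C,
                 double tol, int max_passes, int max_iter) {
  const int n = K.nrow();
  SmoFit fit;
  fit.alpha.assign(n, 0.0);
  fit.b = 0.0;
  fit.iter = 0;
  // E[i] = f(x_i) - y_i ; with alpha = 0, f = 0
  std::vector<double> E(n);
  for (int i = 0; i < n; ++i) E[i] = -y[i];

  // attempts the (i, j) pair update; returns true when alpha moved
  auto take_step = [&](int i, int j) -> bool {
    if (i == j) return false;
    const double ai_old = fit.alpha[i], aj_old = fit.alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (L >= H) return false;
    const double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta >= 0) return false;
    double aj = aj_old - y[j] * (E[i] - E[j]) / eta;
    aj = std::min(H, std::max(L, aj));
    if (std::fabs(aj - aj_old) < 1e-8 * (aj + aj_old + 1e-8)) return false;
    const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    fit.alpha[i] = ai;
    fit.alpha[j] = aj;
    const double b1 = fit.b - E[i] - y[i] * (ai - ai_old) * K(i, i) -
                      y[j] * (aj - aj_old) * K(i, j);
    const double b2 = fit.b - E[j] - y[i] * (ai - ai_old) * K(i, j) -
                      y[j] * (aj - aj_old) * K(j, j);
    double b_new;
    if (ai > 0 && ai < C) b_new = b1;
    else if (aj > 0 && aj < C) b_new = b2;
    else b_new = 0.5 * (b1 + b2);
    const double db = b_new - fit.b;
    fit.b = b_new;
    const double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
    for (int t = 0; t < n; ++t) E[t] += di * K(i, t) + dj * K(j, t) + db;
    ++fit.iter;
    return true;
  };

  int passes = 0;
  while (passes < max_passes && fit.iter < max_iter) {
    int num_changed = 0;
    for (int i = 0; i < n && fit.iter < max_iter; ++i) {
      const double ri = E[i] * y[i];
      if (!((ri < -tol && fit.alpha[i] < C) || (ri > tol && fit.alpha[i] > 0)))
        continue;
      // first choice: maximal |E_i - E_j| (deterministic tie: first index)
      int j = -1;
      double best = -1.0;
      for (int t = 0; t < n; ++t) {
        if (t == i) continue;
        const double d = std::fabs(E[i] - E[t]);
        if (d > best) { best = d; j = t; }
      }
      bool changed = (j >= 0) && take_step(i, j);
      if (!changed) {
        // fallback hierarchy: non-bound partners, then everything,
        // scanned from a deterministic offset
        for (int off = 1; off < n && !changed; ++off) {
          const int t = (i + off) % n;
          if (fit.alpha[t] > 0 && fit.alpha[t] < C) changed = take_step(i, t);
        }
        for (int off = 1; off < n && !changed; ++off) {
          changed = take_step(i, (i + off) % n);
        }
      }
      if (changed) ++num_changed;
    }
    passes = (num_changed == 0) ? passes + 1 : 0;
  }
  return fit;
}

} // namespace

// [[Rcpp::export]]
List smo_train_kernel(NumericMatrix K, IntegerVector y, double C, double tol,
                      int max_passes, int max_iter) {
  std::vector<int> yy(y.begin(), y.end());
  SmoFit fit = smo_solve(K, yy, C, tol, max_passes, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b, _["iter"] = fit.iter);
}

// [[Rcpp::export]]
NumericMatrix rbf_kernel_from_d2(NumericMatrix D2, double sigma) {
  const int n = D2.nrow(), m = D2.ncol();
  NumericMatrix K(n, m);
  const double g = 1.0 / (2.0 * sigma * sigma);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) K(i, j) = std::exp(-D2(i, j) * g);
  return K;
}

// Mean F-score over stratified CV folds for an RBF SVM trained on the given
// squared-distance matrix. Folds with no positive test sample are skipped.
// [[Rcpp::export]]
double cv_fscore_d2(NumericMatrix D2, IntegerVector y, IntegerVector fold,
                    int nfold, double sigma, double C, double tol,
                    int max_passes, int max_iter) {
  const int n = D2.nrow();
  NumericMatrix K = rbf_kernel_from_d2(D2, sigma);
  double fsum = 0.0;
  int fcnt = 0;
  for (int f = 0; f < nfold; ++f) {
    std::vector<int> tr, te;
    tr.reserve(n);
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    if (te.empty() || tr.empty()) continue;
    bool has_pos_test = false, has_pos_tr = false, has_neg_tr = false;
    for (int i : te) if (y[i] > 0) { has_pos_test = true; break; }
    for (int i : tr) { if (y[i] > 0) has_pos_tr = true; else has_neg_tr = true; }
    if (!has_pos_test || !has_pos_tr || !has_neg_tr) continue;
    const int ntr = (int)tr.size();
    NumericMatrix Ksub(ntr, ntr);
    std::vector<int> ysub(ntr);
    for (int a = 0; a < ntr; ++a) {
      ysub[a] = y[tr[a]];
      for (int b = 0; b < ntr; ++b) Ksub(a, b) = K(tr[a], tr[b]);
    }
    SmoFit fit = smo_solve(Ksub, ysub, C, tol, max_passes, max_iter);
    int tp = 0, fp = 0, fn = 0;
    for (int i : te) {
      double s = fit.b;
      for (int a = 0; a < ntr; ++a)
        if (fit.alpha[a] != 0.0) s += fit.alpha[a] * ysub[a] * K(i, tr[a]);
      const bool pred = s > 0;
      if (pred && y[i] > 0) ++tp;
      else if (pred) ++fp;
      else if (y[i] > 0) ++fn;
    }
    const double prec = (tp + fp) ? (double)tp / (tp + fp) : 0.0;
    const double rec = (tp + fn) ? (double)tp / (tp + fn) : 0.0;
    fsum += (prec + rec > 0) ? 2.0 * prec * rec / (prec + rec) : 0.0;
    ++fcnt;
  }
  return fcnt ? fsum / fcnt : 0.0;
}

// [[Rcpp::export]]
NumericMatrix pairwise_sqdist(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix D2(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = X(i, k) - X(j, k);
        s += d * d;
      }
      D2(i, j) = s;
      D2(j, i) = s;
    }
  }
  return D2;
}

// [[Rcpp::export]]
NumericMatrix cross_sqdist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), p = A.ncol();
  NumericMatrix D2(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = A(i, k) - B(j, k);
        s += d * d;
      }
      D2(i, j) = s;
    }
  return D2;
}
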