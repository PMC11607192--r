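// Penalized Cox partial likelihood: Efron/Breslow tie handling, case weights,
// IRLS with diagonal Hessian + coordinate-descent soft thresholding, warm-started
// lambda path. Inputs must be sorted by observed time (ascending); the R wrapper
// owns sorting, standardization and back-transformation of coefficients.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct EtaDeriv {
  std::vector<double> grad;  // d loglik / d eta_i
  std::vector<double> hess;  // -d2 loglik / d eta_i^2 (diagonal approx)
  double loglik;
};

// time ascending; risk set at event time t_k = {i : time[i] >= t_k}.
// Weighted Efron: for a tied death set D_k (d events, weight sum dw),
// loglik contribution = sum_{i in D_k} w_i eta_i
//                       - (dw/d) * sum_{l=0}^{d-1} log(S_k - (l/d) SD_k)
// with S_k, SD_k weighted sums of w e^eta over risk/death sets.
// Breslow drops the l/d correction.
EtaDeriv cox_eta_deriv(const NumericVector& time, const IntegerVector& status,
                       const NumericVector& w, const NumericVector& eta,
                       bool efron) {
  const int n = time.size();
  EtaDeriv out;
  out.grad.assign(n, 0.0);
  out.hess.assign(n, 0.0);
  out.loglik = 0.0;

  std::vector<double> wexp(n);
  for (int i = 0; i < n; ++i) wexp[i] = w[i] * std::exp(eta[i]);

  // suffix sums of wexp: S(i) = sum_{j >= i} wexp[j]  (time ascending)
  std::vector<double> suffix(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suffix[i] = suffix[i + 1] + wexp[i];

  // prefix accumulators over event times t_k <= time[i]
  double cumA = 0.0, cumB = 0.0;
  std::vector<double> A(n, 0.0), B(n, 0.0);

  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && time[j] == time[i]) ++j;  // tie block [i, j)
    // death set within the block
    double SD = 0.0, dw = 0.0, sum_w_eta = 0.0;
    int d = 0;
    for (int k = i; k < j; ++k) {
      if (status[k] == 1) {
        SD += wexp[k];
        dw += w[k];
        sum_w_eta += w[k] * eta[k];
        ++d;
      }
    }
    if (d > 0) {
      const double S = suffix[i];
      double addA = 0.0, addB = 0.0;      // coefficient-1 parts
      double tieA = 0.0, tieB2 = 0.0;     // death-set corrections
      const double m = dw / d;            // multiplier per Efron term
      for (int l = 0; l < d; ++l) {
        const double frac = efron ? (double)l / d : 0.0;
        const double denom = S - frac * SD;
        out.loglik -= m * std::log(denom);
        addA += m / denom;
        addB += m / (denom * denom);
        // for i in D_k: c = 1 - frac; c/denom and c^2/denom^2 instead
        tieA += m * frac / denom;
        tieB2 += m * (2.0 * frac - frac * frac) / (denom * denom);
      }
      out.loglik += sum_w_eta;
      cumA += addA;
      cumB += addB;
      for (int k = i; k < j; ++k) {
        A[k] = cumA;
        B[k] = cumB;
        if (status[k] == 1) { A[k] -= tieA; B[k] -= tieB2; }
      }
    } else {
      for (int k = i; k < j; ++k) { A[k] = cumA; B[k] = cumB; }
    }
    i = j;
  }
  // subjects with time > all processed event times already carry the full
  // prefix because A/B were assigned inside their own tie block
  for (int k = 0; k < n; ++k) {
    const double g = (status[k] == 1 ? w[k] : 0.0) - wexp[k] * A[k];
    double h = wexp[k] * A[k] - wexp[k] * wexp[k] * B[k];
    if (h < 1e-12) h = 1e-12;
    out.grad[k] = g;
    out.hess[k] = h;
  }
  return out;
}

inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cox_deriv(NumericVector time, IntegerVector status, NumericVector w,
                   NumericVector eta, bool efron) {
  EtaDeriv d = cox_eta_deriv(time, status, w, eta, efron);
  return List::create(_["grad"] = wrap(d.grad), _["hess"] = wrap(d.hess),
                      _["loglik"] = d.loglik);
}

// Fit a decreasing lambda path on standardized X (sorted by time ascending).
// Penalty: minimize -(1/W) loglik + lambda * sum(|beta|), W = sum(w).
// [[Rcpp::export]]
List cpp_cox_path(NumericMatrix X, NumericVector time, IntegerVector status,
                  NumericVector w, NumericVector lambda, bool efron,
                  double tol, int maxit_outer, int maxit_inner) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += w[i];

  NumericMatrix beta_out(p, L);
  LogicalVector converged(L);
  NumericVector loglik_out(L);

  std::vector<double> beta(p, 0.0), eta(n, 0.0);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    bool conv = false;
    std::vector<double> beta_entry = beta, eta_entry = eta;
    bool diverged = false;
    for (int outer = 0; outer < maxit_outer; ++outer) {
      EtaDeriv d = cox_eta_deriv(time, status,
                                 NumericVector(w), NumericVector(wrap(eta)),
                                 efron);
      // working response z_i = eta_i + g_i / h_i; weights h_i
      // precompute per-column h-weighted x'x diagonal
      std::vector<double> r(n);  // h * (z - eta) = g, then update as residual
      for (int i = 0; i < n; ++i) r[i] = d.grad[i];
      std::vector<double> xx(p, 0.0);
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += d.hess[i] * X(i, j) * X(i, j);
        xx[j] = s / W;
      }
      double max_step = 0.0;
      for (int inner = 0; inner < maxit_inner; ++inner) {
        max_step = 0.0;
        double bmax_in = 0.0;
        for (int j = 0; j < p; ++j) {
          if (xx[j] <= 0) continue;
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
          g /= W;
          const double bj_new = soft(g + xx[j] * beta[j], lam) / xx[j];
          const double diff = bj_new - beta[j];
          if (diff != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d.hess[i] * X(i, j) * diff;
            beta[j] = bj_new;
            const double st = std::fabs(diff);
            if (st > max_step) max_step = st;
          }
          if (std::fabs(beta[j]) > bmax_in) bmax_in = std::fabs(beta[j]);
        }
        if (bmax_in > 100.0 || !std::isfinite(max_step)) { diverged = true; break; }
        if (max_step < tol) break;
      }
      if (diverged) break;
      // divergence guard: monotone likelihood (p >> events) sends |beta|
      // to infinity along the unpenalized end of the path
      double bmax = 0.0;
      for (int j = 0; j < p; ++j) {
        if (!std::isfinite(beta[j])) { diverged = true; break; }
        if (std::fabs(beta[j]) > bmax) bmax = std::fabs(beta[j]);
      }
      if (diverged || bmax > 100.0) { diverged = true; break; }
      // refresh eta, check outer convergence on eta change
      double max_eta_change = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
        const double ch = std::fabs(e - eta[i]);
        if (ch > max_eta_change) max_eta_change = ch;
        eta[i] = e;
      }
      if (max_eta_change < tol * 10) { conv = true; break; }
    }
    if (diverged) { beta = beta_entry; eta = eta_entry; conv = false; }
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    converged[l] = conv;
    EtaDeriv df = cox_eta_deriv(time, status, NumericVector(w),
                                NumericVector(wrap(eta)), efron);
    loglik_out[l] = df.loglik;
  }
  return List::create(_["beta"] = beta_out, _["converged"] = converged,
                      _["loglik"] = loglik_out);
}
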