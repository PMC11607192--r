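// Uno's IPCW concordance. Pair rule: i contributes when status_i = 1,
// time_i < time_j and time_i < tau; pair weight 1/G(time_i-)^2 is supplied by
// the caller as ginv2 (censoring-distribution Kaplan-Meier, left limits).
// Concordant when score_i > score_j (higher score = higher risk); score ties
// count 1/2. SE is a leave-one-subject-out jackknife over the pair sums with
// the censoring weights held fixed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_uno_c(NumericVector time, IntegerVector status, NumericVector score,
               NumericVector ginv2, double tau, bool jackknife) {
  const int n = time.size();
  double num = 0.0, den = 0.0;
  std::vector<double> num_i(n, 0.0), den_i(n, 0.0);

  for (int i = 0; i < n; ++i) {
    if (status[i] != 1 || time[i] >= tau) continue;
    const double w = ginv2[i];
    for (int j = 0; j < n; ++j) {
      if (time[j] <= time[i]) continue;
      double conc = 0.0;
      if (score[i] > score[j]) conc = 1.0;
      else if (score[i] == score[j]) conc = 0.5;
      num += w * conc;
      den += w;
      num_i[i] += w * conc; den_i[i] += w;
      num_i[j] += w * conc; den_i[j] += w;
    }
  }
  if (den <= 0.0)
    return List::create(_["c"] = NA_REAL, _["se"] = NA_REAL,
                        _["num"] = num, _["den"] = den, _["n_pairs_used"] = 0.0);
  const double c = num / den;
  double se = NA_REAL;
  if (jackknife && n > 1) {
    std::vector<double> cj(n);
    double cbar = 0.0;
    for (int k = 0; k < n; ++k) {
      const double dk = den - den_i[k];
      cj[k] = dk > 0.0 ? (num - num_i[k]) / dk : c;
      cbar += cj[k];
    }
    cbar /= n;
    double ss = 0.0;
    for (int k = 0; k < n; ++k) ss += (cj[k] - cbar) * (cj[k] - cbar);
    se = std::sqrt((double)(n - 1) / n * ss);
  }
  return List::create(_["c"] = c, _["se"] = se, _["num"] = num, _["den"] = den,
                      _["n_pairs_used"] = den > 0 ? 1.0 : 0.0);
}

// Concordance of each column of a score matrix (shared time/status/weights);
// used by cross-validation over a lambda path.
// [[Rcpp::export]]
NumericVector cpp_uno_c_multi(NumericVector time, IntegerVector status,
                              NumericMatrix scores, NumericVector ginv2,
                              double tau) {
  const int n = time.size(), L = scores.ncol();
  NumericVector out(L);
  // Precompute usable pairs once
  std::vector<int> pi, pj;
  std::vector<double> pw;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1 || time[i] >= tau) continue;
    for (int j = 0; j < n; ++j) {
      if (time[j] <= time[i]) continue;
      pi.push_back(i); pj.push_back(j); pw.push_back(ginv2[i]);
    }
  }
  const int P = pi.size();
  for (int l = 0; l < L; ++l) {
    double num = 0.0, den = 0.0;
    for (int k = 0; k < P; ++k) {
      const double si = scores(pi[k], l), sj = scores(pj[k], l);
      double conc = si > sj ? 1.0 : (si == sj ? 0.5 : 0.0);
      num += pw[k] * conc;
      den += pw[k];
    }
    out[l] = den > 0.0 ? num / den : NA_REAL;
  }
  return out;
}
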