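// Linear-chain CRF recursions in log space: forward-backward
// (partition function, per-position marginals, summed pairwise
// transition expectations) and Viterbi decoding. Label count K is
// small (8), sequence lengths a few hundred.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lse(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// emis: L x K log emission scores; trans: K x K log transition scores
// [[Rcpp::export]]
List crf_fb_cpp(NumericMatrix emis, NumericMatrix trans) {
  const int L = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(L, K), beta(L, K), marg(L, K), pair(K, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) alpha(0, k) = emis(0, k);
  for (int t = 1; t < L; ++t)
    for (int b = 0; b < K; ++b) {
      for (int a = 0; a < K; ++a) tmp[a] = alpha(t - 1, a) + trans(a, b);
      alpha(t, b) = emis(t, b) + lse(tmp);
    }

  for (int k = 0; k < K; ++k) beta(L - 1, k) = 0.0;
  for (int t = L - 2; t >= 0; --t)
    for (int a = 0; a < K; ++a) {
      for (int b = 0; b < K; ++b)
        tmp[b] = trans(a, b) + emis(t + 1, b) + beta(t + 1, b);
      beta(t, a) = lse(tmp);
    }

  for (int k = 0; k < K; ++k) tmp[k] = alpha(L - 1, k);
  const double logZ = lse(tmp);

  for (int t = 0; t < L; ++t)
    for (int k = 0; k < K; ++k)
      marg(t, k) = std::exp(alpha(t, k) + beta(t, k) - logZ);

  for (int t = 1; t < L; ++t)
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b)
        pair(a, b) += std::exp(alpha(t - 1, a) + trans(a, b) +
                               emis(t, b) + beta(t, b) - logZ);

  return List::create(_["logZ"] = logZ, _["marginals"] = marg,
                      _["pair_expect"] = pair);
}

// [[Rcpp::export]]
List crf_viterbi_cpp(NumericMatrix emis, NumericMatrix trans) {
  const int L = emis.nrow(), K = emis.ncol();
  NumericMatrix delta(L, K);
  IntegerMatrix back(L, K);

  for (int k = 0; k < K; ++k) delta(0, k) = emis(0, k);
  for (int t = 1; t < L; ++t)
    for (int b = 0; b < K; ++b) {
      double best = delta(t - 1, 0) + trans(0, b);
      int arg = 0;
      for (int a = 1; a < K; ++a) {
        const double s = delta(t - 1, a) + trans(a, b);
        if (s > best) { best = s; arg = a; }
      }
      delta(t, b) = emis(t, b) + best;
      back(t, b) = arg;
    }

  double best = delta(L - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(L - 1, k) > best) { best = delta(L - 1, k); arg = k; }

  IntegerVector path(L);
  path[L - 1] = arg;
  for (int t = L - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < L; ++t) path[t] += 1;  // 1-based labels

  return List::create(_["path"] = path, _["score"] = best);
}
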