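#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double logsumexp(const double* v, int n) {
  double m = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i)
    if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Exact chain inference over a linear-chain model with per-locus local
// evidence L (T x K, log scale) and per-gap transition log-potentials
// log(1-theta[t]) on the diagonal, log(theta[t]/(K-1)) off-diagonal.
//
// pref: 0-based state indices in tie-breaking preference order for the
// Viterbi argmax (first strictly-greater wins, so earlier preference states
// win exact ties).
//
// Returns the Viterbi path (1-based state indices), the best final score
// max_y delta_T(y), the log-normalizer log Z(x), and row-normalized
// posterior marginals from forward-backward.
// [[Rcpp::export(name = ".crp_chain_dp")]]
List crp_chain_dp(NumericMatrix L, NumericVector log_stay,
                  NumericVector log_switch, IntegerVector pref) {
  const int T = L.nrow(), K = L.ncol();
  if (T < 1 || K < 2) stop("need T >= 1 and K >= 2");
  if (log_stay.size() != T - 1 || log_switch.size() != T - 1)
    stop("transition vectors must have length T - 1");

  NumericMatrix delta(T, K), alpha(T, K), beta(T, K);
  IntegerMatrix back(T, K);
  std::vector<double> work(K);

  for (int k = 0; k < K; ++k) {
    delta(0, k) = L(0, k);
    alpha(0, k) = L(0, k);
  }

  for (int t = 1; t < T; ++t) {
    const double st = log_stay[t - 1], sw = log_switch[t - 1];
    // logsumexp over previous states splits into the diagonal term and the
    // off-diagonal ones, but K is tiny: do it directly.
    for (int k = 0; k < K; ++k) {
      // Viterbi max with preference-ordered tie-break
      double best = -std::numeric_limits<double>::infinity();
      int arg = pref[0];
      for (int pi = 0; pi < K; ++pi) {
        int j = pref[pi];
        double cand = delta(t - 1, j) + (j == k ? st : sw);
        if (cand > best) {
          best = cand;
          arg = j;
        }
      }
      delta(t, k) = L(t, k) + best;
      back(t, k) = arg;
      for (int j = 0; j < K; ++j)
        work[j] = alpha(t - 1, j) + (j == k ? st : sw);
      alpha(t, k) = L(t, k) + logsumexp(work.data(), K);
    }
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    const double st = log_stay[t], sw = log_switch[t];
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k)
        work[k] = (j == k ? st : sw) + L(t + 1, k) + beta(t + 1, k);
      beta(t, j) = logsumexp(work.data(), K);
    }
  }

  for (int k = 0; k < K; ++k) work[k] = alpha(T - 1, k);
  const double log_Z = logsumexp(work.data(), K);

  // best final state, preference-ordered
  double delta_final = -std::numeric_limits<double>::infinity();
  int last = pref[0];
  for (int pi = 0; pi < K; ++pi) {
    int k = pref[pi];
    if (delta(T - 1, k) > delta_final) {
      delta_final = delta(T - 1, k);
      last = k;
    }
  }
  IntegerVector path(T);
  path[T - 1] = last + 1;
  for (int t = T - 1; t > 0; --t) {
    last = back(t, last);
    path[t - 1] = last + 1;
  }

  NumericMatrix post(T, K);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) work[k] = alpha(t, k) + beta(t, k);
    double norm = logsumexp(work.data(), K);
    for (int k = 0; k < K; ++k) post(t, k) = std::exp(work[k] - norm);
  }

  return List::create(
      _["path"] = path, _["delta_final"] = delta_final, _["log_Z"] = log_Z,
      _["posteriors"] = post);
}
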