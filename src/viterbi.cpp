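#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a homogeneous HMM with Gaussian emissions.
// Returns the 0-based maximum-probability state path and its log-probability.
// [[Rcpp::export]]
List viterbi_path_cpp(NumericVector x, NumericVector state_means,
                      double emission_sd, NumericMatrix log_trans,
                      NumericVector log_init) {
  const int n = x.size();
  const int K = state_means.size();
  if (n == 0) return List::create(_["path"] = IntegerVector(0),
                                  _["logp"] = R_NegInf);

  NumericMatrix delta(K, n);
  IntegerMatrix psi(K, n);
  const double lconst = -0.5 * std::log(2.0 * M_PI) - std::log(emission_sd);
  const double inv2v = 1.0 / (2.0 * emission_sd * emission_sd);

  for (int k = 0; k < K; ++k) {
    double z = x[0] - state_means[k];
    delta(k, 0) = log_init[k] + lconst - z * z * inv2v;
  }
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(0, t - 1) + log_trans(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double cand = delta(j, t - 1) + log_trans(j, k);
        if (cand > best) { best = cand; arg = j; }
      }
      double z = x[t] - state_means[k];
      delta(k, t) = best + lconst - z * z * inv2v;
      psi(k, t) = arg;
    }
  }

  IntegerVector path(n);
  double best = delta(0, n - 1);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(k, n - 1) > best) { best = delta(k, n - 1); arg = k; }
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(path[t], t);

  return List::create(_["path"] = path, _["logp"] = best);
}
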