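#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-time HMM.
// logdens: T x S matrix of per-observation log emission densities.
// Returns log-likelihood, smoothed state probabilities gamma (T x S) and
// summed transition expectations xi (S x S), as needed by one EM step.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericVector init,
                          NumericMatrix trans) {
  const int T = logdens.nrow(), S = logdens.ncol();
  NumericMatrix b(T, S), alpha(T, S), beta(T, S), gamma(T, S), xi(S, S);
  NumericVector m(T), c(T);
  for (int t = 0; t < T; ++t) {
    double mx = logdens(t, 0);
    for (int s = 1; s < S; ++s) mx = std::max(mx, logdens(t, s));
    m[t] = mx;
    for (int s = 0; s < S; ++s) b(t, s) = std::exp(logdens(t, s) - mx);
  }
  // forward
  double ll = 0.0;
  for (int s = 0; s < S; ++s) alpha(0, s) = init[s] * b(0, s);
  c[0] = 0; for (int s = 0; s < S; ++s) c[0] += alpha(0, s);
  if (c[0] <= 0) c[0] = 1e-300;
  for (int s = 0; s < S; ++s) alpha(0, s) /= c[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0;
    for (int s = 0; s < S; ++s) {
      double a = 0;
      for (int r = 0; r < S; ++r) a += alpha(t - 1, r) * trans(r, s);
      a *= b(t, s);
      alpha(t, s) = a;
      ct += a;
    }
    if (ct <= 0) ct = 1e-300;
    c[t] = ct;
    for (int s = 0; s < S; ++s) alpha(t, s) /= ct;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + m[t];
  // backward
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int r = 0; r < S; ++r) {
      double v = 0;
      for (int s = 0; s < S; ++s)
        v += trans(r, s) * b(t + 1, s) * beta(t + 1, s);
      beta(t, r) = v / c[t + 1];
    }
  // gamma and xi sums
  for (int t = 0; t < T; ++t) {
    double tot = 0;
    for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); tot += gamma(t, s); }
    if (tot > 0) for (int s = 0; s < S; ++s) gamma(t, s) /= tot;
  }
  for (int t = 0; t < T - 1; ++t)
    for (int r = 0; r < S; ++r)
      for (int s = 0; s < S; ++s)
        xi(r, s) += alpha(t, r) * trans(r, s) * b(t + 1, s) * beta(t + 1, s) / c[t + 1];
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericVector log_init,
                          NumericMatrix log_trans) {
  const int T = logdens.nrow(), S = logdens.ncol();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; ++s) delta(0, s) = log_init[s] + logdens(0, s);
  for (int t = 1; t < T; ++t)
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf; int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta(t - 1, r) + log_trans(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta(t, s) = best + logdens(t, s);
      psi(t, s) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int s = 0; s < S; ++s)
    if (delta(T - 1, s) > best) { best = delta(T - 1, s); path[T - 1] = s; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;
}
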