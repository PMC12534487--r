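#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one observation sequence.
//
// logB: T x K matrix of log emission densities log b_k(x_t).
// A:    K x K row-stochastic transition matrix.
// init: length-K initial distribution.
//
// Emission likelihoods are shifted by the per-row maximum before
// exponentiation, so the recursion stays finite for log-densities as low
// as -1e6; the shifts are added back into the log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix A, NumericVector init) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix Bt(T, K);
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) Bt(t, k) = std::exp(logB(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * Bt(0, k); s += alpha(0, k); }
  if (!(s > 0.0)) stop("forward pass underflowed at t = 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= Bt(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (!(s > 0.0)) stop("forward pass underflowed at t = %d", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * Bt(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + shift[t];

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  const int Tm1 = T > 1 ? T - 1 : 0;
  NumericVector xi(Dimension(Tm1, K, K));
  for (int t = 0; t < Tm1; ++t) {
    double z = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, i) * A(i, j) * Bt(t + 1, j) * beta(t + 1, j) / c[t + 1];
        xi[t + Tm1 * (i + K * j)] = v;
        z += v;
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi[t + Tm1 * (i + K * j)] /= z;
  }

  return List::create(_["log_likelihood"] = ll,
                      _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Log-space Viterbi recursion; ties broken toward the lower state index
// (strict > comparison keeps the first maximiser). Returns a 1-based path.
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }

  int last = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); last = k; }

  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["log_prob"] = best);
}
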