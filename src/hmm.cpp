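#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one chain.
// logB: T x K per-volume emission log-densities; A: K x K row-stochastic
// transition; pi: initial distribution. Scaling constants keep everything in
// double range; the log-likelihood is exact (sum of log scaling constants
// plus the per-row shifts taken out of logB).
// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi, bool return_xi = false) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K);
  NumericVector cvec(T), shift(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); c0 += alpha(0, k); }
  if (c0 <= 0.0) stop("forward pass underflow at t = 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = s * B(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0.0) stop("forward pass underflow at t = %d", t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    cvec[t] = ct;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + shift[t];

  // backward (scaled by the same constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / cvec[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi_sum(K, K);
  NumericVector xi_full;
  if (return_xi) xi_full = NumericVector(Dimension(T > 1 ? T - 1 : 0, K, K));
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    // xi(t, j, k) proportional to alpha_t(j) A(j,k) B_{t+1}(k) beta_{t+1}(k)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        s += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / s;
        xi_sum(j, k) += v;
        if (return_xi) xi_full[t + (T - 1) * (j + K * k)] = v;
      }
  }

  List out = List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                          _["loglik"] = loglik);
  if (return_xi) out["xi"] = xi_full;
  return out;
}

// Viterbi decoding in log space; returns 1-based state indices.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix logA(K, K);
  NumericVector logpi(K);
  for (int k = 0; k < K; ++k) logpi[k] = std::log(pi[k]);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) logA(j, k) = std::log(A(j, k));

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
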