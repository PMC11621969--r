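#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for an HMM given a T x N matrix of per-day log
// emission densities. Rows for missing days must be all zero (emission
// vector of ones), which leaves the transition structure intact.
// Returns the total log likelihood.
// [[Rcpp::export(name = ".fwd_loglik_cpp")]]
double fwd_loglik_cpp(NumericMatrix logdens, NumericVector delta,
                      NumericMatrix Gamma) {
  const int T = logdens.nrow(), N = logdens.ncol();
  std::vector<double> phi(N), nphi(N);
  double ll = 0.0;

  // t = 0
  double m = logdens(0, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(0, j));
  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    phi[j] = delta[j] * std::exp(logdens(0, j) - m);
    s += phi[j];
  }
  if (s <= 0.0) return R_NegInf;
  ll += std::log(s) + m;
  for (int j = 0; j < N; ++j) phi[j] /= s;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(t, j));
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += phi[i] * Gamma(i, j);
      nphi[j] = a * std::exp(logdens(t, j) - m);
      s += nphi[j];
    }
    if (s <= 0.0) return R_NegInf;
    ll += std::log(s) + m;
    for (int j = 0; j < N; ++j) phi[j] = nphi[j] / s;
  }
  return ll;
}

// Viterbi decoding in log space. Ties are broken towards the lower state
// index (strict inequality when scanning in increasing index order).
// Returns 1-based most-likely state indices for all T days.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector delta,
                          NumericMatrix Gamma) {
  const int T = logdens.nrow(), N = logdens.ncol();
  NumericMatrix v(T, N);
  IntegerMatrix bp(T, N);
  for (int j = 0; j < N; ++j)
    v(0, j) = (delta[j] > 0 ? std::log(delta[j]) : R_NegInf) + logdens(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < N; ++i) {
        double lg = Gamma(i, j) > 0 ? std::log(Gamma(i, j)) : R_NegInf;
        double cand = v(t - 1, i) + lg;
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logdens(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int j = 0; j < N; ++j)
    if (v(T - 1, j) > best) { best = v(T - 1, j); arg = j; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = bp(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Full negative log likelihood for the pooled fit: emission densities are
// rebuilt from per-state parameters using precomputed log(step), cos(turn)
// and sin(turn), then the scaled forward recursion runs per bird segment.
// Missing components contribute 0 to the log emission density.
// [[Rcpp::export(name = ".negloglik_cpp")]]
double negloglik_cpp(NumericVector step, NumericVector logstep,
                     NumericVector costurn, NumericVector sinturn,
                     LogicalVector step_ok, LogicalVector turn_ok,
                     IntegerVector seg_start, IntegerVector seg_len,
                     NumericVector delta, NumericMatrix Gamma,
                     NumericVector mean, NumericVector sd,
                     NumericVector zmass, NumericVector mu,
                     NumericVector kappa) {
  const int N = mean.size();
  const double log2pi = std::log(2.0 * M_PI);
  std::vector<double> shape(N), rate(N), cgam(N), czero(N), ck(N),
      cosmu(N), sinmu(N);
  for (int j = 0; j < N; ++j) {
    shape[j] = mean[j] * mean[j] / (sd[j] * sd[j]);
    rate[j] = mean[j] / (sd[j] * sd[j]);
    cgam[j] = std::log1p(-zmass[j]) + shape[j] * std::log(rate[j]) -
              R::lgammafn(shape[j]);
    czero[j] = zmass[j] > 0 ? std::log(zmass[j]) : R_NegInf;
    // log I0(kappa) via the exponentially scaled Bessel function
    ck[j] = -log2pi - (std::log(R::bessel_i(kappa[j], 0.0, 2.0)) + kappa[j]);
    cosmu[j] = std::cos(mu[j]);
    sinmu[j] = std::sin(mu[j]);
  }
  double ll = 0.0;
  std::vector<double> phi(N), nphi(N), ld(N);
  for (int b = 0; b < seg_start.size(); ++b) {
    const int s0 = seg_start[b], T = seg_len[b];
    bool first = true;
    for (int t = 0; t < T; ++t) {
      const int i = s0 + t;
      double m = R_NegInf;
      for (int j = 0; j < N; ++j) {
        double e = 0.0;
        if (step_ok[i]) {
          if (step[i] == 0.0) e += czero[j];
          else e += cgam[j] + (shape[j] - 1.0) * logstep[i] - rate[j] * step[i];
        }
        if (turn_ok[i])
          e += kappa[j] * (cosmu[j] * costurn[i] + sinmu[j] * sinturn[i]) + ck[j];
        ld[j] = e;
        if (e > m) m = e;
      }
      double s = 0.0;
      if (first) {
        for (int j = 0; j < N; ++j) {
          phi[j] = delta[j] * std::exp(ld[j] - m);
          s += phi[j];
        }
        first = false;
      } else {
        for (int j = 0; j < N; ++j) {
          double a = 0.0;
          for (int k = 0; k < N; ++k) a += phi[k] * Gamma(k, j);
          nphi[j] = a * std::exp(ld[j] - m);
          s += nphi[j];
        }
        for (int j = 0; j < N; ++j) phi[j] = nphi[j];
      }
      if (s <= 0.0 || !std::isfinite(s)) return R_PosInf;
      ll += std::log(s) + m;
      for (int j = 0; j < N; ++j) phi[j] /= s;
    }
  }
  return -ll;
}
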