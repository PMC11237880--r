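#include <Rcpp.h>
using namespace Rcpp;

// All recursions run in log space; per-step reductions use log-sum-exp so the
// forward/backward messages stay finite for arbitrarily long runs.

static inline double logsumexp_row(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward-backward smoother for one run.
// logb: T x K log observation densities, loga: K x K log transition,
// logpi: K log initial probabilities.
// Returns gamma (T x K), xi ((T-1) x K*K, row t holds xi[t][j,k] column-major
// in (j,k), i.e. entry j + K*k) and the log evidence.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logb, NumericMatrix loga,
                          NumericVector logpi) {
  const int T = logb.nrow(), K = logb.ncol();
  NumericMatrix la(T, K), lb(T, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logb(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = la(t - 1, j) + loga(j, k);
      la(t, k) = logb(t, k) + logsumexp_row(tmp);
    }
  }
  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k)
        tmp[k] = loga(j, k) + logb(t + 1, k) + lb(t + 1, k);
      lb(t, j) = logsumexp_row(tmp);
    }
  }

  for (int k = 0; k < K; ++k) tmp[k] = la(T - 1, k);
  const double logz = logsumexp_row(tmp);

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - logz);
      rs += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= rs; // guard rounding drift
  }

  NumericMatrix xi(std::max(T - 1, 0), K * K);
  for (int t = 0; t + 1 < T; ++t) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) {
        double v = std::exp(la(t, j) + loga(j, k) + logb(t + 1, k) +
                            lb(t + 1, k) - logz);
        xi(t, j + K * k) = v;
        rs += v;
      }
    }
    for (int i = 0; i < K * K; ++i) xi(t, i) /= rs;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["log_evidence"] = logz);
}

// Viterbi decoding, ties broken toward the lower state index.
// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix logb, NumericMatrix loga, NumericVector logpi) {
  const int T = logb.nrow(), K = logb.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logb(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + loga(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + loga(j, k);
        if (v > best) { best = v; arg = j; } // strict: ties keep lower j
      }
      delta(t, k) = best + logb(t, k);
      psi(t, k) = arg;
    }
  }

  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1; // 1-based state labels

  return List::create(_["path"] = path, _["log_prob"] = best);
}

// Markov chain sampler on a fixed grid: u is a vector of pre-drawn uniforms
// (length T), cum is the K x K row-wise cumulative transition matrix and
// cum0 the cumulative initial distribution.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericVector u, NumericMatrix cum,
                               NumericVector cum0) {
  const int T = u.size(), K = cum.ncol();
  IntegerVector s(T);
  int cur = 0;
  while (cur < K - 1 && u[0] > cum0[cur]) ++cur;
  s[0] = cur + 1;
  for (int t = 1; t < T; ++t) {
    int k = 0;
    while (k < K - 1 && u[t] > cum(cur, k)) ++k;
    cur = k;
    s[t] = cur + 1;
  }
  return s;
}
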