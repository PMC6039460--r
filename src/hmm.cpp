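#include <Rcpp.h>
using namespace Rcpp;

// Sparse-transition HMM over the DNA alphabet, log space.
// obs: 0=A,1=C,2=G,3=T, 4=N. N emits with probability 1 in every state
// (score-neutral). logEmis: nstates x 4. Transitions as parallel edge
// lists (0-based from/to) with log probabilities. logPi: initial
// distribution.

static inline double emit(const NumericMatrix& logEmis, int s, int o) {
  return o == 4 ? 0.0 : logEmis(s, o);
}

// [[Rcpp::export(name = ".hmm_viterbi")]]
List hmm_viterbi(IntegerVector obs, NumericMatrix logEmis,
                 IntegerVector efrom, IntegerVector eto, NumericVector elp,
                 NumericVector logPi) {
  const int n = obs.size(), S = logEmis.nrow(), E = efrom.size();
  if (n == 0) return List::create(_["path"] = IntegerVector(0), _["logprob"] = 0.0);
  // group in-edges by target state
  std::vector<std::vector<int>> in(S);
  for (int e = 0; e < E; ++e) in[eto[e]].push_back(e);
  std::vector<double> v(S), vn(S);
  std::vector<int> bt(static_cast<size_t>(n) * S);
  for (int s = 0; s < S; ++s) v[s] = logPi[s] + emit(logEmis, s, obs[0]);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf; int arg = -1;
      for (int k : in[s]) {
        double cand = v[efrom[k]] + elp[k];
        if (cand > best) { best = cand; arg = efrom[k]; }
      }
      vn[s] = best + emit(logEmis, s, obs[t]);
      bt[static_cast<size_t>(t) * S + s] = arg;
    }
    std::swap(v, vn);
  }
  double best = R_NegInf; int arg = 0;
  for (int s = 0; s < S; ++s) if (v[s] > best) { best = v[s]; arg = s; }
  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) {
    arg = bt[static_cast<size_t>(t) * S + arg];
    path[t - 1] = arg;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".hmm_forward")]]
double hmm_forward(IntegerVector obs, NumericMatrix logEmis,
                   IntegerVector efrom, IntegerVector eto, NumericVector elp,
                   NumericVector logPi) {
  const int n = obs.size(), S = logEmis.nrow(), E = efrom.size();
  if (n == 0) return 0.0;
  std::vector<std::vector<int>> in(S);
  for (int e = 0; e < E; ++e) in[eto[e]].push_back(e);
  std::vector<double> f(S), fn(S);
  for (int s = 0; s < S; ++s) f[s] = logPi[s] + emit(logEmis, s, obs[0]);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      double acc = R_NegInf;
      for (int k : in[s]) acc = logsumexp2(acc, f[efrom[k]] + elp[k]);
      fn[s] = acc + emit(logEmis, s, obs[t]);
    }
    std::swap(f, fn);
  }
  double tot = R_NegInf;
  for (int s = 0; s < S; ++s) tot = logsumexp2(tot, f[s]);
  return tot;
}

// Posterior state occupancies P(state_t = s | obs), n x S matrix.
// [[Rcpp::export(name = ".hmm_posterior")]]
NumericMatrix hmm_posterior(IntegerVector obs, NumericMatrix logEmis,
                            IntegerVector efrom, IntegerVector eto,
                            NumericVector elp, NumericVector logPi) {
  const int n = obs.size(), S = logEmis.nrow(), E = efrom.size();
  std::vector<std::vector<int>> in(S), out(S);
  for (int e = 0; e < E; ++e) { in[eto[e]].push_back(e); out[efrom[e]].push_back(e); }
  NumericMatrix fa(n, S), ba(n, S);
  for (int s = 0; s < S; ++s) fa(0, s) = logPi[s] + emit(logEmis, s, obs[0]);
  for (int t = 1; t < n; ++t)
    for (int s = 0; s < S; ++s) {
      double acc = R_NegInf;
      for (int k : in[s]) acc = logsumexp2(acc, fa(t - 1, efrom[k]) + elp[k]);
      fa(t, s) = acc + emit(logEmis, s, obs[t]);
    }
  for (int s = 0; s < S; ++s) ba(n - 1, s) = 0.0;
  for (int t = n - 2; t >= 0; --t)
    for (int s = 0; s < S; ++s) {
      double acc = R_NegInf;
      for (int k : out[s])
        acc = logsumexp2(acc, elp[k] + emit(logEmis, eto[k], obs[t + 1]) + ba(t + 1, eto[k]));
      ba(t, s) = acc;
    }
  double tot = R_NegInf;
  for (int s = 0; s < S; ++s) tot = logsumexp2(tot, fa(n - 1, s));
  NumericMatrix post(n, S);
  for (int t = 0; t < n; ++t)
    for (int s = 0; s < S; ++s)
      post(t, s) = std::exp(fa(t, s) + ba(t, s) - tot);
  return post;
}
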