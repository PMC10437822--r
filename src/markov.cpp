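#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-1 Markov chain over {A,C,G,T}.
// `trans` is the 4x4 row-stochastic transition matrix (rows = current
// state), `start` the start distribution, and `u` a vector of n uniforms
// supplied by the caller (drawn from R's RNG, so the chain is reproducible
// under set.seed()).
// [[Rcpp::export(name = ".markov_chain_cpp")]]
std::string markov_chain_cpp(NumericMatrix trans, NumericVector start,
                             NumericVector u) {
  const int n = u.size();
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');
  if (n == 0) return out;

  double cum_start[4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += start[j]; cum_start[j] = acc; }

  double cum[4][4];
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); cum[i][j] = acc; }
  }

  int s = 3;
  for (int j = 0; j < 4; ++j) if (u[0] <= cum_start[j]) { s = j; break; }
  out[0] = bases[s];
  for (int t = 1; t < n; ++t) {
    const double v = u[t];
    int nx = 3;
    for (int j = 0; j < 4; ++j) if (v <= cum[s][j]) { nx = j; break; }
    out[t] = bases[nx];
    s = nx;
  }
  return out;
}
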