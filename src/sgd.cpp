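#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// L2-regularized hinge-loss linear model trained by stochastic gradient
// descent (Pegasos-style 1/(lambda*t) step), on a CSR document-term matrix.
// y in {-1,+1}. Deterministic: Fisher-Yates shuffles driven by splitmix64.

struct SM {
  uint64_t s;
  explicit SM(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// [[Rcpp::export]]
List cpp_sgd_hinge(IntegerVector row_ptr, IntegerVector col_idx,
                   NumericVector vals, NumericVector y, int n_features,
                   int epochs, double lambda, int seed) {
  int n = y.size();
  std::vector<double> w(n_features, 0.0);
  double b = 0.0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  SM rng((uint64_t)seed * 0x2545F4914F6CDD1DULL + 11ULL);
  long long t = 1;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int ii = 0; ii < n; ++ii, ++t) {
      int i = order[ii];
      double eta = 1.0 / (lambda * (t + 100.0));
      double margin = b;
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        margin += w[col_idx[k]] * vals[k];
      margin *= y[i];
      // weight decay (applied lazily would be faster; n is small here)
      double decay = 1.0 - eta * lambda;
      if (decay < 0) decay = 0;
      for (int c = 0; c < n_features; ++c) w[c] *= decay;
      if (margin < 1.0) {
        for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
          w[col_idx[k]] += eta * y[i] * vals[k];
        b += eta * y[i] * 0.01;
      }
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b);
}
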