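#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling (word2vec SGNS), single worker so that a
// fixed seed yields identical vectors.  docs hold 0-based word ids; counts
// are corpus frequencies used for the 3/4-power negative-sampling table.
// Returns a V x dim input-embedding matrix.

struct SM64 {
  uint64_t s;
  explicit SM64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List docs, IntegerVector counts, int dim,
                             int window, int negative, int epochs,
                             double lr0, int seed) {
  int V = counts.size();
  int D = docs.size();
  SM64 rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

  // unigram^0.75 table for negative draws
  const int TBL = 1 << 20;
  std::vector<int> table(TBL);
  {
    std::vector<double> pw(V);
    double tot = 0.0;
    for (int v = 0; v < V; ++v) { pw[v] = std::pow((double)counts[v], 0.75); tot += pw[v]; }
    double acc = pw[0] / tot;
    int v = 0;
    for (int i = 0; i < TBL; ++i) {
      double u = (i + 0.5) / TBL;
      while (u > acc && v < V - 1) { ++v; acc += pw[v] / tot; }
      table[i] = v;
    }
  }

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  long long total_tokens = 0;
  for (int d = 0; d < D; ++d) total_tokens += ((IntegerVector)docs[d]).size();
  long long budget = total_tokens * (long long)epochs;
  long long seen = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < D; ++d) {
      IntegerVector dv = docs[d];
      int n = dv.size();
      for (int i = 0; i < n; ++i) {
        double lr = lr0 * (1.0 - (double)seen / (budget + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++seen;
        int b = (int)(rng.unif() * window);
        if (b == window) b = window - 1;
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          int wi = dv[j];       // input word (context position)
          int wo = dv[i];       // predicted word
          double* v_in = &syn0[(size_t)wi * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) { target = wo; label = 1.0; }
            else {
              target = table[rng.next() & (TBL - 1)];
              if (target == wo) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int c = 0; c < dim; ++c) f += v_in[c] * v_out[c];
            double g = (label - sigmoid(f)) * lr;
            for (int c = 0; c < dim; ++c) {
              grad[c] += g * v_out[c];
              v_out[c] += g * v_in[c];
            }
          }
          for (int c = 0; c < dim; ++c) v_in[c] += grad[c];
        }
      }
      if (d % 1000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < dim; ++c) out(v, c) = syn0[(size_t)v * dim + c];
  return out;
}
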