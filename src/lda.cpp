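#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG independent of library implementations: xoshiro-style
// splitmix64 stream mapped to [0,1).  Keeps Gibbs draws bit-identical across
// platforms for a fixed seed.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline int sample_cat(const std::vector<double>& p, double total,
                             SplitMix& rng) {
  double u = rng.unif() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u < acc) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of 0-based word-id integer vectors. Returns topic-word and
// doc-topic count matrices from the final sweep.
// [[Rcpp::export]]
List cpp_lda_fit(List docs, int V, int K, double alpha, double beta,
                 int n_iter, int seed) {
  int D = docs.size();
  std::vector<std::vector<int> > w(D), z(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
  }
  std::vector<int> nwk((size_t)V * K, 0), ndk((size_t)D * K, 0), nk(K, 0);
  SplitMix rng((uint64_t)seed * 2654435761ULL + 1ULL);

  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(rng.unif() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++nwk[(size_t)w[d][i] * K + k];
      ++ndk[(size_t)d * K + k];
      ++nk[k];
    }
  }

  std::vector<double> p(K);
  double Vb = V * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      int* nd = &ndk[(size_t)d * K];
      for (size_t i = 0; i < w[d].size(); ++i) {
        int wid = w[d][i];
        int k = z[d][i];
        int* nw = &nwk[(size_t)wid * K];
        --nw[k]; --nd[k]; --nk[k];
        double tot = 0.0;
        for (int t = 0; t < K; ++t) {
          double v = (nw[t] + beta) / (nk[t] + Vb) * (nd[t] + alpha);
          p[t] = v;
          tot += v;
        }
        k = sample_cat(p, tot, rng);
        z[d][i] = k;
        ++nw[k]; ++nd[k]; ++nk[k];
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix topic_word(K, V), doc_topic(D, K);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < K; ++k) topic_word(k, v) = nwk[(size_t)v * K + k];
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) doc_topic(d, k) = ndk[(size_t)d * K + k];
  return List::create(_["topic_word_counts"] = topic_word,
                      _["doc_topic_counts"] = doc_topic);
}

// Fold-in inference against a frozen topic-word distribution phi (K x V).
// Returns D x K doc-topic proportions (counts + alpha, normalized).
// [[Rcpp::export]]
NumericMatrix cpp_lda_infer(List docs, NumericMatrix phi, double alpha,
                            int n_iter, int seed) {
  int D = docs.size();
  int K = phi.nrow();
  NumericMatrix theta(D, K);
  SplitMix rng((uint64_t)seed * 0x9e3779b9ULL + 7ULL);
  std::vector<double> p(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    int n = dv.size();
    if (n == 0) {
      for (int k = 0; k < K; ++k) theta(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> zd(n);
    std::vector<int> nd(K, 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)(rng.unif() * K);
      if (k == K) k = K - 1;
      zd[i] = k;
      ++nd[k];
    }
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < n; ++i) {
        int wid = dv[i];
        int k = zd[i];
        --nd[k];
        double tot = 0.0;
        for (int t = 0; t < K; ++t) {
          double v = phi(t, wid) * (nd[t] + alpha);
          p[t] = v;
          tot += v;
        }
        if (tot > 0) {
          k = sample_cat(p, tot, rng);
        } else {
          k = (int)(rng.unif() * K);
          if (k == K) k = K - 1;
        }
        zd[i] = k;
        ++nd[k];
      }
    }
    double denom = n + K * alpha;
    for (int k = 0; k < K; ++k) theta(d, k) = (nd[k] + alpha) / denom;
    if (d % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  return theta;
}
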