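#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
// priors. Single chain, single thread; deterministic under the seed.
// Returns the final-sweep count matrices; posterior-mean smoothing is
// applied on the R side.

// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(List docs, int vocab_size, int K, double alpha, double beta,
               int n_iter, int seed) {
  const int V = vocab_size;
  const int D = docs.size();
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  std::vector<std::vector<int>> w(D);
  std::vector<std::vector<int>> z(D);
  std::vector<int> n_dk((size_t)D * K, 0);
  std::vector<int> n_kw((size_t)K * V, 0);
  std::vector<int> n_k(K, 0);

  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d] = std::vector<int>(dv.begin(), dv.end());
    z[d].resize(dv.size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int topic = (int)(unif01(rng) * K);
      if (topic == K) topic = K - 1;
      z[d][i] = topic;
      ++n_dk[(size_t)d * K + topic];
      ++n_kw[(size_t)topic * V + w[d][i]];
      ++n_k[topic];
    }
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int word = w[d][i];
        int topic = z[d][i];
        --n_dk[(size_t)d * K + topic];
        --n_kw[(size_t)topic * V + word];
        --n_k[topic];

        double cum = 0.0;
        for (int k = 0; k < K; ++k) {
          cum += (n_dk[(size_t)d * K + k] + alpha) *
                 (n_kw[(size_t)k * V + word] + beta) / (n_k[k] + Vbeta);
          p[k] = cum;
        }
        double u = unif01(rng) * cum;
        topic = 0;
        while (topic < K - 1 && p[topic] < u) ++topic;

        z[d][i] = topic;
        ++n_dk[(size_t)d * K + topic];
        ++n_kw[(size_t)topic * V + word];
        ++n_k[topic];
      }
    }
  }

  IntegerMatrix dk(D, K), kw(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k)
      dk(d, k) = n_dk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      kw(k, v) = n_kw[(size_t)k * V + v];
  return List::create(_["n_dk"] = dk, _["n_kw"] = kw);
}
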