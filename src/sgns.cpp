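#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and fully deterministic
// under the supplied seed. Sentences arrive as 0-based integer id vectors;
// the unigram^(3/4) negative-sampling distribution is sampled by inverse
// CDF so no approximation table is needed at these vocabulary sizes.

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size,
                         NumericVector counts, int dim, int window,
                         int epochs, int negative, double alpha,
                         double min_alpha, int seed) {
  const int V = vocab_size, D = dim;
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  // inverse-CDF table for the unigram^0.75 noise distribution
  std::vector<double> cdf(V);
  double tot = 0.0;
  for (int w = 0; w < V; ++w) {
    tot += std::pow(counts[w], 0.75);
    cdf[w] = tot;
  }
  for (int w = 0; w < V; ++w) cdf[w] /= tot;

  auto draw_negative = [&]() {
    double u = unif01(rng);
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  // syn0 ~ U(-0.5/D, 0.5/D), syn1 = 0 (word2vec initialisation)
  std::vector<double> syn0((size_t)V * D), syn1((size_t)V * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / D;

  long long total_words = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> sents(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector sv = sentences[s];
    sents[s] = std::vector<int>(sv.begin(), sv.end());
    total_words += sv.size();
  }
  const long long train_total = total_words * (long long)epochs;
  long long processed = 0;

  std::vector<double> grad(D);
  std::uniform_int_distribution<int> win_draw(1, window);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sent = sents[s];
      const int n = (int)sent.size();
      for (int pos = 0; pos < n; ++pos) {
        double lr = alpha -
          (alpha - min_alpha) * ((double)processed / (double)train_total);
        ++processed;
        const int center = sent[pos];
        const int b = win_draw(rng);  // dynamic window
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[(size_t)context * D];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = draw_negative();
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * D];
            double dot = 0.0;
            for (int k = 0; k < D; ++k) dot += v_in[k] * v_out[k];
            double g = (label - sigmoid_clip(dot)) * lr;
            for (int k = 0; k < D; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < D; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, D);
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < D; ++k)
      out(w, k) = syn0[(size_t)w * D + k];
  return out;
}
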