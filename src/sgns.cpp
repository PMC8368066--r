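// Skip-gram negative-sampling trainer. Single-threaded, deterministic given
// the seed: private xorshift64* RNG, fixed update order (instances in stream
// order, centers left to right, contexts left to right within the window).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

namespace {

struct Xorshift64s {
  uint64_t s;
  explicit Xorshift64s(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 1e-13;
  return 1.0 / (1.0 + std::exp(-x));
}

// index of first cdf element > u (cdf is increasing, last element 1)
inline int sample_cdf(const std::vector<double>& cdf, double u) {
  return (int)(std::upper_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

} // namespace

// tokens: 0-based vocabulary ids, all instances concatenated
// offsets: 0-based start offset of each instance, plus total length (n_inst+1)
// noise_cdf: cumulative unigram^0.75 noise distribution over the vocabulary
// [[Rcpp::export(name = ".sgns_train_cpp")]]
Rcpp::List sgns_train_cpp(Rcpp::IntegerVector tokens,
                          Rcpp::IntegerVector offsets,
                          int vocab_size,
                          Rcpp::NumericVector noise_cdf,
                          int window, int dim, int epochs, int negatives,
                          double alpha0, double alpha_min,
                          double seed) {
  const int n_inst = offsets.size() - 1;
  std::vector<double> cdf(noise_cdf.begin(), noise_cdf.end());
  Xorshift64s rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // input (center) and output (context) embeddings
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // total pair count, for the linear learning-rate schedule
  long long pairs_per_epoch = 0;
  for (int s = 0; s < n_inst; ++s) {
    long long L = offsets[s + 1] - offsets[s];
    for (long long i = 0; i < L; ++i) {
      long long lo = std::max((long long)0, i - window);
      long long hi = std::min(L - 1, i + window);
      pairs_per_epoch += hi - lo; // excludes i itself
    }
  }
  if (pairs_per_epoch == 0)
    Rcpp::stop("training stream yields no (center, context) pairs");
  const double total_pairs = (double)pairs_per_epoch * epochs;

  std::vector<double> grad(dim);
  Rcpp::NumericVector loss_trace(epochs);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int s = 0; s < n_inst; ++s) {
      const int start = offsets[s], stop = offsets[s + 1];
      const int L = stop - start;
      for (int i = 0; i < L; ++i) {
        const int w = tokens[start + i];
        double* v = &syn0[(size_t)w * dim];
        const int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          const int c = tokens[start + j];
          const double alpha =
            alpha0 + (alpha_min - alpha0) * ((double)processed / total_pairs);
          std::fill(grad.begin(), grad.end(), 0.0);
          // positive sample
          {
            double* u = &syn1[(size_t)c * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += u[d] * v[d];
            const double sg = sigmoid(dot);
            ep_loss -= std::log(std::max(sg, 1e-13));
            const double g = (1.0 - sg) * alpha; // -d loss / d dot, scaled
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * u[d];
              u[d] += g * v[d];
            }
          }
          // negative samples from the unigram^0.75 noise distribution
          for (int k = 0; k < negatives && vocab_size > 1; ++k) {
            int n = c;
            for (int tries = 0; n == c && tries < 100; ++tries)
              n = sample_cdf(cdf, rng.unif());
            if (n == c) continue;
            double* u = &syn1[(size_t)n * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += u[d] * v[d];
            const double sg = sigmoid(dot);
            ep_loss -= std::log(std::max(1.0 - sg, 1e-13));
            const double g = -sg * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * u[d];
              u[d] += g * v[d];
            }
          }
          for (int d = 0; d < dim; ++d) v[d] += grad[d];
          ++processed;
        }
      }
    }
    if (!std::isfinite(ep_loss))
      Rcpp::stop("non-finite SGNS loss at epoch %d; reduce the learning rate", ep + 1);
    loss_trace[ep] = ep_loss / (double)pairs_per_epoch;
  }

  Rcpp::NumericMatrix vectors(vocab_size, dim), context(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d) {
      vectors(w, d) = syn0[(size_t)w * dim + d];
      context(w, d) = syn1[(size_t)w * dim + d];
    }
  return Rcpp::List::create(Rcpp::Named("vectors") = vectors,
                            Rcpp::Named("context_vectors") = context,
                            Rcpp::Named("loss_trace") = loss_trace);
}
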