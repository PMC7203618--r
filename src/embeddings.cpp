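// Joint skip-gram negative-sampling (SGNS) and PV-DBOW trainer.
//
// Word input vectors are trained with SGNS over sliding contexts; document
// vectors are trained with PV-DBOW against the SAME output (context) layer,
// so document-by-word inner products D W^T are affinities in a shared space.
// Single-threaded and driven by an own xorshift RNG so results are
// bit-reproducible for a given seed, independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s0, s1;
  explicit XorShift(uint64_t seed) {
    // splitmix64 to spread the seed
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9e3779b97f4a7c15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0 - 1e-7;
  if (x < -8.0) return 1e-7;
  return 1.0 / (1.0 + std::exp(-x));
}

// negative sample by binary search on the cumulative noise distribution
inline int sample_noise(const std::vector<double>& cum, XorShift& rng) {
  double u = rng.unif() * cum.back();
  int lo = 0, hi = static_cast<int>(cum.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// One negative-sampling update: input vector v predicts output vector of
// `target` (label 1) plus `negatives` noise words (label 0). Gradients on v
// are accumulated in `acc` (applied by the caller); output vectors updated
// in place unless `freeze_out` (inference mode).
inline void ns_update(double* v, std::vector<double>& out, int k, int target,
                      int negatives, const std::vector<double>& cum,
                      double alpha, XorShift& rng, std::vector<double>& acc,
                      bool freeze_out = false) {
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int s = 0; s <= negatives; ++s) {
    int w;
    double label;
    if (s == 0) {
      w = target;
      label = 1.0;
    } else {
      w = sample_noise(cum, rng);
      if (w == target) continue;
      label = 0.0;
    }
    double* u = &out[static_cast<size_t>(w) * k];
    double dot = 0.0;
    for (int c = 0; c < k; ++c) dot += v[c] * u[c];
    double g = (label - sigmoid_clip(dot)) * alpha;
    for (int c = 0; c < k; ++c) {
      acc[c] += g * u[c];
      if (!freeze_out) u[c] += g * v[c];
    }
  }
  for (int c = 0; c < k; ++c) v[c] += acc[c];
}

} // namespace

// [[Rcpp::export(name = ".train_embeddings_cpp")]]
List train_embeddings_cpp(List docs, NumericVector noise, int n_words, int k,
                          int window, int negatives, int epochs,
                          double alpha0, double min_alpha, int seed) {
  std::vector<std::vector<int>> corpus(docs.size());
  long long total_tokens = 0;
  for (int d = 0; d < docs.size(); ++d) {
    IntegerVector v = docs[d];
    corpus[d].assign(v.begin(), v.end());
    total_tokens += v.size();
  }
  std::vector<double> cum(noise.size());
  double acc_noise = 0.0;
  for (int i = 0; i < noise.size(); ++i) {
    acc_noise += noise[i];
    cum[i] = acc_noise;
  }

  XorShift rng(static_cast<uint64_t>(seed));
  const int m = static_cast<int>(corpus.size());
  std::vector<double> w_in(static_cast<size_t>(n_words) * k);
  std::vector<double> w_out(static_cast<size_t>(n_words) * k);
  std::vector<double> dvec(static_cast<size_t>(m) * k);
  for (auto& x : w_in) x = (rng.unif() - 0.5) / k;
  // random (small) init of the shared context layer keeps it well
  // conditioned, which the closed-form document-vector solution relies on
  for (auto& x : w_out) x = (rng.unif() - 0.5) / std::sqrt((double)k);
  for (auto& x : dvec) x = (rng.unif() - 0.5) / k;

  std::vector<double> acc(k);
  long long processed = 0;
  const long long planned = std::max<long long>(1, total_tokens * epochs);
  double alpha = alpha0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < m; ++d) {
      const std::vector<int>& doc = corpus[d];
      const int len = static_cast<int>(doc.size());
      double* dv = &dvec[static_cast<size_t>(d) * k];
      for (int t = 0; t < len; ++t) {
        alpha = alpha0 - (alpha0 - min_alpha) *
          (static_cast<double>(processed) / planned);
        ++processed;
        const int target = doc[t];
        // PV-DBOW: document vector predicts the word at position t
        ns_update(dv, w_out, k, target, negatives, cum, alpha, rng, acc);
        // SGNS: context words predict the word at position t
        if (window > 0 && len > 1) {
          int b = 1 + rng.below(window);
          for (int c = std::max(0, t - b); c <= std::min(len - 1, t + b); ++c) {
            if (c == t) continue;
            double* cv = &w_in[static_cast<size_t>(doc[c]) * k];
            ns_update(cv, w_out, k, target, negatives, cum, alpha, rng, acc);
          }
        }
      }
    }
  }

  NumericMatrix W(n_words, k), Wout(n_words, k), D(m, k);
  for (int i = 0; i < n_words; ++i)
    for (int c = 0; c < k; ++c) {
      W(i, c) = w_in[static_cast<size_t>(i) * k + c];
      Wout(i, c) = w_out[static_cast<size_t>(i) * k + c];
    }
  for (int d = 0; d < m; ++d)
    for (int c = 0; c < k; ++c) D(d, c) = dvec[static_cast<size_t>(d) * k + c];
  return List::create(_["W"] = W, _["Wout"] = Wout, _["D"] = D);
}
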