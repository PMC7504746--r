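// Shallow neural word-embedding trainer: CBOW and skip-gram with negative
// sampling, single-threaded with its own multiplicative-congruential RNG so
// results are bit-reproducible for a given seed regardless of R's RNG state.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct W2VRng {
  unsigned long long state;
  explicit W2VRng(unsigned long long seed) : state(seed ? seed : 1ULL) {}
  unsigned long long next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 16 & 0xFFFFFFFFULL) / 4294967296.0; }
  int below(int n) { return (int)(next() % (unsigned long long)n); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative unigram^0.75 table for negative sampling, inverse-CDF sampled
// by binary search (vocabulary sizes here are modest)
std::vector<double> noise_cdf(const IntegerVector& counts) {
  int V = counts.size();
  std::vector<double> cdf(V);
  double acc = 0.0;
  for (int i = 0; i < V; ++i) {
    acc += std::pow((double)counts[i], 0.75);
    cdf[i] = acc;
  }
  for (int i = 0; i < V; ++i) cdf[i] /= acc;
  return cdf;
}

int sample_noise(const std::vector<double>& cdf, W2VRng& rng) {
  double u = rng.unif();
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List w2v_train_cpp(List sentences, IntegerVector counts, int dim, int window,
                   int negative, int epochs, double initial_lr,
                   double final_lr, double sample, bool cbow, int seed) {
  const int V = counts.size();
  W2VRng rng((unsigned long long)seed);

  std::vector<double> syn0((size_t)V * dim);   // input vectors
  std::vector<double> syn1((size_t)V * dim, 0.0);  // context (output) vectors
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> cdf = noise_cdf(counts);
  double train_words = 0.0;
  for (int i = 0; i < V; ++i) train_words += counts[i];
  const double total = std::max(1.0, train_words * (double)epochs);

  std::vector<double> neu1(dim), neu1e(dim);
  std::vector<int> sent;
  double processed = 0.0;
  const int S = sentences.size();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < S; ++si) {
      IntegerVector s = sentences[si];
      // frequency subsampling (word2vec keep-probability formula)
      sent.clear();
      for (int j = 0; j < s.size(); ++j) {
        int w = s[j];
        processed += 1.0;
        if (sample > 0) {
          double f = counts[w];
          double keep = (std::sqrt(f / (sample * train_words)) + 1.0) *
                        (sample * train_words) / f;
          if (keep < 1.0 && rng.unif() >= keep) continue;
        }
        sent.push_back(w);
      }
      const int n = (int)sent.size();
      if (n == 0) continue;
      double lr = initial_lr * (1.0 - processed / total);
      if (lr < final_lr) lr = final_lr;

      for (int pos = 0; pos < n; ++pos) {
        const int center = sent[pos];
        const int b = rng.below(window);        // effective window in 1..window
        const int win = window - b;
        const int lo = std::max(0, pos - win);
        const int hi = std::min(n - 1, pos + win);

        if (cbow) {
          int cn = 0;
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            const double* v = &syn0[(size_t)sent[p] * dim];
            for (int d = 0; d < dim; ++d) neu1[d] += v[d];
            ++cn;
          }
          if (cn == 0) continue;
          for (int d = 0; d < dim; ++d) neu1[d] /= cn;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = center; label = 1.0; }
            else {
              target = sample_noise(cdf, rng);
              if (target == center) continue;
              label = 0.0;
            }
            double* c = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += neu1[d] * c[d];
            const double g = (label - sigmoid(f)) * lr;
            for (int d = 0; d < dim; ++d) neu1e[d] += g * c[d];
            for (int d = 0; d < dim; ++d) c[d] += g * neu1[d];
          }
          for (int d = 0; d < dim; ++d) neu1e[d] /= cn;
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            double* v = &syn0[(size_t)sent[p] * dim];
            for (int d = 0; d < dim; ++d) v[d] += neu1e[d];
          }
        } else {  // skip-gram: predict each context word from the center
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            double* v = &syn0[(size_t)center * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int k = 0; k <= negative; ++k) {
              int target; double label;
              if (k == 0) { target = sent[p]; label = 1.0; }
              else {
                target = sample_noise(cdf, rng);
                if (target == sent[p]) continue;
                label = 0.0;
              }
              double* c = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int d = 0; d < dim; ++d) f += v[d] * c[d];
              const double g = (label - sigmoid(f)) * lr;
              for (int d = 0; d < dim; ++d) neu1e[d] += g * c[d];
              for (int d = 0; d < dim; ++d) c[d] += g * v[d];
            }
            for (int d = 0; d < dim; ++d) v[d] += neu1e[d];
          }
        }
      }
    }
  }

  NumericMatrix input(V, dim), context(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) {
      input(i, d) = syn0[(size_t)i * dim + d];
      context(i, d) = syn1[(size_t)i * dim + d];
    }
  return List::create(_["input"] = input, _["context"] = context);
}

// Negative-sampling loss and analytic gradients for one training example,
// with the negative samples supplied explicitly. Used by the
// numerical-gradient check; the math mirrors the SGD updates above
// (update = -lr * gradient).
// [[Rcpp::export(rng = false)]]
List w2v_loss_grad_cpp(NumericMatrix input, NumericMatrix context,
                       int center, IntegerVector ctx, IntegerVector negs,
                       bool cbow) {
  const int V = input.nrow(), dim = input.ncol();
  NumericMatrix gin(V, dim), gctx(V, dim);
  double loss = 0.0;

  if (cbow) {
    const int cn = ctx.size();
    std::vector<double> h(dim, 0.0), gh(dim, 0.0);
    for (int j = 0; j < cn; ++j)
      for (int d = 0; d < dim; ++d) h[d] += input(ctx[j], d);
    for (int d = 0; d < dim; ++d) h[d] /= cn;
    for (int k = -1; k < (int)negs.size(); ++k) {
      const int target = (k < 0) ? center : negs[k];
      const double label = (k < 0) ? 1.0 : 0.0;
      double f = 0.0;
      for (int d = 0; d < dim; ++d) f += h[d] * context(target, d);
      const double sg = sigmoid(f);
      loss += (k < 0) ? -std::log(std::max(sg, 1e-300))
                      : -std::log(std::max(1.0 - sg, 1e-300));
      const double e = sg - label;  // dL/df
      for (int d = 0; d < dim; ++d) {
        gh[d] += e * context(target, d);
        gctx(target, d) += e * h[d];
      }
    }
    for (int j = 0; j < cn; ++j)
      for (int d = 0; d < dim; ++d) gin(ctx[j], d) += gh[d] / cn;
  } else {
    // loss summed over (center -> each context word) pairs, sharing negs
    for (int j = 0; j < ctx.size(); ++j) {
      std::vector<double> gv(dim, 0.0);
      for (int k = -1; k < (int)negs.size(); ++k) {
        const int target = (k < 0) ? ctx[j] : negs[k];
        const double label = (k < 0) ? 1.0 : 0.0;
        double f = 0.0;
        for (int d = 0; d < dim; ++d) f += input(center, d) * context(target, d);
        const double sg = sigmoid(f);
        loss += (k < 0) ? -std::log(std::max(sg, 1e-300))
                        : -std::log(std::max(1.0 - sg, 1e-300));
        const double e = sg - label;
        for (int d = 0; d < dim; ++d) {
          gv[d] += e * context(target, d);
          gctx(target, d) += e * input(center, d);
        }
      }
      for (int d = 0; d < dim; ++d) gin(center, d) += gv[d];
    }
  }
  return List::create(_["loss"] = loss, _["grad_input"] = gin,
                      _["grad_context"] = gctx);
}

// Mean negative-sampling loss over a corpus with seeded dynamic windows and
// noise draws (no subsampling), so the same seed scores two models on the
// identical set of (example, negatives) draws.
// [[Rcpp::export(rng = false)]]
double w2v_mean_loss_cpp(NumericMatrix input, NumericMatrix context,
                         List sentences, IntegerVector counts, int window,
                         int negative, bool cbow, int seed) {
  const int dim = input.ncol();
  W2VRng rng((unsigned long long)seed);
  std::vector<double> cdf = noise_cdf(counts);
  double loss = 0.0;
  long n_examples = 0;
  std::vector<double> h(dim);

  for (int si = 0; si < sentences.size(); ++si) {
    IntegerVector s = sentences[si];
    const int n = s.size();
    for (int pos = 0; pos < n; ++pos) {
      const int center = s[pos];
      const int b = rng.below(window);
      const int win = window - b;
      const int lo = std::max(0, pos - win);
      const int hi = std::min(n - 1, pos + win);
      if (cbow) {
        int cn = 0;
        std::fill(h.begin(), h.end(), 0.0);
        for (int p = lo; p <= hi; ++p) {
          if (p == pos) continue;
          for (int d = 0; d < dim; ++d) h[d] += input(s[p], d);
          ++cn;
        }
        if (cn == 0) continue;
        for (int d = 0; d < dim; ++d) h[d] /= cn;
        for (int k = 0; k <= negative; ++k) {
          int target; double label;
          if (k == 0) { target = center; label = 1.0; }
          else {
            target = sample_noise(cdf, rng);
            if (target == center) continue;
            label = 0.0;
          }
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += h[d] * context(target, d);
          const double sg = sigmoid(f);
          loss += (label > 0.5) ? -std::log(std::max(sg, 1e-300))
                                : -std::log(std::max(1.0 - sg, 1e-300));
        }
        ++n_examples;
      } else {
        for (int p = lo; p <= hi; ++p) {
          if (p == pos) continue;
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = s[p]; label = 1.0; }
            else {
              target = sample_noise(cdf, rng);
              if (target == s[p]) continue;
              label = 0.0;
            }
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += input(center, d) * context(target, d);
            const double sg = sigmoid(f);
            loss += (label > 0.5) ? -std::log(std::max(sg, 1e-300))
                                  : -std::log(std::max(1.0 - sg, 1e-300));
          }
          ++n_examples;
        }
      }
    }
  }
  return n_examples ? loss / n_examples : 0.0;
}
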