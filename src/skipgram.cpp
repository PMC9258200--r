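#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// SkipGram with negative sampling over a walk corpus.
//
// Matches the classic word2vec SGD scheme: for each position the center
// token is predicted from each context token inside a per-position dynamic
// window (uniform in [1, window]); one positive and `negative` sampled
// updates per pair; linear learning-rate decay. Negative samples are drawn
// from the unigram distribution raised to the 3/4 power. All randomness
// comes from R's RNG (single-threaded), so results are reproducible from
// set.seed().
//
// walks: n_walks x walk_length matrix of 1-based node indices.
// Returns the n_nodes x dim input-embedding matrix.
// [[Rcpp::export]]
NumericMatrix sg_train_cpp(IntegerMatrix walks, int n_nodes, int dim,
                           int window, int epochs, int negative,
                           double alpha0, double min_alpha) {
  const int n_walks = walks.nrow();
  const int len = walks.ncol();

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> counts(n_nodes, 0.0);
  for (int w = 0; w < n_walks; ++w)
    for (int t = 0; t < len; ++t)
      counts[walks(w, t) - 1] += 1.0;
  std::vector<double> cum(n_nodes, 0.0);
  double total = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    total += std::pow(counts[i], 0.75);
    cum[i] = total;
  }

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif_rand() - 0.5) / dim;

  auto sample_neg = [&]() -> int {
    double u = unif_rand() * total;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  const double total_pairs =
      (double)epochs * (double)n_walks * (double)len;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      for (int t = 0; t < len; ++t) {
        double alpha = alpha0 * (1.0 - processed / total_pairs);
        if (alpha < min_alpha) alpha = min_alpha;
        processed += 1.0;
        int center = walks(w, t) - 1;
        int b = 1 + (int)(unif_rand() * window);  // dynamic window in [1, window]
        if (b > window) b = window;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int pos = t + off;
          if (pos < 0 || pos >= len) continue;
          int context = walks(w, pos) - 1;
          double *in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = sample_neg();
              if (target == center) continue;
              label = 0.0;
            }
            double *out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += in[k] * out[k];
            double f = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - f) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * out[k];
              out[k] += g * in[k];
            }
          }
          for (int k = 0; k < dim; ++k) in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix result(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k)
      result(i, k) = syn0[(size_t)i * dim + k];
  return result;
}
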