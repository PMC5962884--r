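// Collapsed Gibbs sampler for the standard mixture-of-topics model.
// Uses R's RNG so runs are reproducible via set.seed() in the R wrapper.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_lda_cpp(List docs, int k, int vocab_size, double alpha, double beta,
                   int iterations, int burn_in) {
  const int D = docs.size();
  std::vector<std::vector<int>> w(D);
  std::vector<std::vector<int>> z(D);
  NumericMatrix ndk(D, k);            // doc-topic counts
  NumericMatrix nkw(k, vocab_size);   // topic-word counts
  NumericVector nk(k);                // topic totals

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    w[d].assign(doc.begin(), doc.end());
    z[d].resize(doc.size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int t = (int)std::floor(unif_rand() * k);
      if (t == k) t = k - 1;
      z[d][i] = t;
      ndk(d, t) += 1;
      nkw(t, w[d][i]) += 1;
      nk[t] += 1;
    }
  }

  NumericMatrix theta_acc(D, k);
  NumericMatrix phi_acc(k, vocab_size);
  int n_samples = 0;
  std::vector<double> p(k);
  const double vbeta = vocab_size * beta;

  for (int it = 0; it < iterations; ++it) {
    for (int d = 0; d < D; ++d) {
      const int len = (int)w[d].size();
      for (int i = 0; i < len; ++i) {
        const int word = w[d][i];
        int t = z[d][i];
        ndk(d, t) -= 1; nkw(t, word) -= 1; nk[t] -= 1;
        double tot = 0.0;
        for (int j = 0; j < k; ++j) {
          p[j] = (ndk(d, j) + alpha) * (nkw(j, word) + beta) / (nk[j] + vbeta);
          tot += p[j];
        }
        double u = unif_rand() * tot;
        int tnew = 0;
        double cum = p[0];
        while (u > cum && tnew < k - 1) { cum += p[++tnew]; }
        z[d][i] = tnew;
        ndk(d, tnew) += 1; nkw(tnew, word) += 1; nk[tnew] += 1;
      }
    }
    if (it >= burn_in) {
      ++n_samples;
      for (int d = 0; d < D; ++d) {
        const double len = (double)w[d].size();
        for (int j = 0; j < k; ++j)
          theta_acc(d, j) += (ndk(d, j) + alpha) / (len + k * alpha);
      }
      for (int j = 0; j < k; ++j)
        for (int v = 0; v < vocab_size; ++v)
          phi_acc(j, v) += (nkw(j, v) + beta) / (nk[j] + vbeta);
    }
  }

  if (n_samples == 0) n_samples = 1;  // guarded in R; avoid div by zero
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < k; ++j) theta_acc(d, j) /= n_samples;
  for (int j = 0; j < k; ++j)
    for (int v = 0; v < vocab_size; ++v) phi_acc(j, v) /= n_samples;

  return List::create(_["theta"] = theta_acc, _["phi"] = phi_acc,
                      _["n_samples"] = n_samples);
}
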