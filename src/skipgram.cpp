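// SkipGram trainer with hierarchical softmax, the inner loop of DeepWalk.
// Single-threaded on purpose: identical seeds must give bit-identical
// embeddings, and corpora from association networks are small.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// walks: list of 1-based integer vectors over node indices 1..V
// paths/codes: per node, the internal-node indices (1-based, into psi rows)
//   and branch codes (0/1) from root to the node's leaf
// phi: V x n (updated in place on a clone), psi: (V-1) x n likewise
// [[Rcpp::export]]
List skipgram_train_cpp(List walks, List paths, List codes,
                        NumericMatrix phi_in, NumericMatrix psi_in,
                        int window, int epochs, double lr0, double lr_min) {
  NumericMatrix phi = clone(phi_in);
  NumericMatrix psi = clone(psi_in);
  const int n = phi.ncol();
  const int nwalk = walks.size();

  // total (center, context) pair count drives the linear lr decay
  long long total = 0;
  for (int k = 0; k < nwalk; ++k) {
    IntegerVector w = walks[k];
    int L = w.size();
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      total += (hi - lo);  // excludes j == i
    }
  }
  total *= std::max(1, epochs);
  if (total == 0)
    return List::create(_["phi"] = phi, _["psi"] = psi);

  std::vector<double> neu1e(n);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int k = 0; k < nwalk; ++k) {
      IntegerVector w = walks[k];
      int L = w.size();
      for (int i = 0; i < L; ++i) {
        int center = w[i] - 1;
        int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          double lr = lr0 - (lr0 - lr_min) * ((double)done / (double)total);
          if (lr < lr_min) lr = lr_min;
          ++done;
          int ctx = w[j] - 1;  // leaf whose root-path is descended
          IntegerVector path = paths[ctx];
          IntegerVector code = codes[ctx];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int l = 0; l < path.size(); ++l) {
            int b = path[l] - 1;
            double x = 0.0;
            for (int d = 0; d < n; ++d) x += phi(center, d) * psi(b, d);
            double g = (1.0 - code[l] - sigmoid(x)) * lr;
            for (int d = 0; d < n; ++d) {
              neu1e[d] += g * psi(b, d);
              psi(b, d) += g * phi(center, d);
            }
          }
          for (int d = 0; d < n; ++d) phi(center, d) += neu1e[d];
        }
      }
    }
  }
  return List::create(_["phi"] = phi, _["psi"] = psi);
}

// Mean negative log-likelihood of the corpus under the current parameters:
// average over all (center, context) pairs of -log Pr(context | phi(center)).
// [[Rcpp::export]]
double skipgram_loss_cpp(List walks, List paths, List codes,
                         NumericMatrix phi, NumericMatrix psi, int window) {
  const int n = phi.ncol();
  long double loss = 0.0;
  long long pairs = 0;
  for (int k = 0; k < walks.size(); ++k) {
    IntegerVector w = walks[k];
    int L = w.size();
    for (int i = 0; i < L; ++i) {
      int center = w[i] - 1;
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      for (int j = lo; j <= hi; ++j) {
        if (j == i) continue;
        ++pairs;
        int ctx = w[j] - 1;
        IntegerVector path = paths[ctx];
        IntegerVector code = codes[ctx];
        for (int l = 0; l < path.size(); ++l) {
          int b = path[l] - 1;
          double x = 0.0;
          for (int d = 0; d < n; ++d) x += phi(center, d) * psi(b, d);
          double s = (code[l] == 0) ? x : -x;
          // -log sigmoid(s), numerically stable
          loss += (s > 0) ? std::log1p(std::exp(-s)) : (-s + std::log1p(std::exp(s)));
        }
      }
    }
  }
  if (pairs == 0) return NA_REAL;
  return (double)(loss / pairs);
}
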