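#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Randomized regression-tree ensemble importance (Extra-Trees variant).
// For one target y and a matrix X of candidate regulators, grows nTrees
// fully randomized trees: at each node, mtry candidate features are drawn
// without replacement, each gets one uniform random cut point between its
// node-local min and max, and the cut with the largest reduction in the
// sum of squares is kept. The importance of a feature is the total sum
// of squares reduction it achieves, averaged over trees. A deterministic
// Mersenne Twister seeded from R makes results reproducible.

struct NodeJob {
  std::vector<int> idx;
};

// [[Rcpp::export(name = ".etImportanceCpp")]]
NumericVector etImportanceCpp(NumericMatrix X, NumericVector y,
                              int nTrees, int mtry, int minNode,
                              int seed) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector imp(p);
  if (n < 2 || p < 1 || nTrees < 1) return imp;
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (minNode < 2) minNode = 2;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> featPool(p);

  for (int t = 0; t < nTrees; ++t) {
    std::vector<NodeJob> stack;
    NodeJob root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    stack.push_back(std::move(root));

    while (!stack.empty()) {
      NodeJob job = std::move(stack.back());
      stack.pop_back();
      const std::vector<int>& idx = job.idx;
      const int m = (int)idx.size();
      if (m < minNode) continue;
      double sum = 0.0, sumsq = 0.0;
      for (int i = 0; i < m; ++i) {
        double v = y[idx[i]];
        sum += v; sumsq += v * v;
      }
      double ssNode = sumsq - sum * sum / m;
      if (ssNode <= 1e-12) continue;

      // draw mtry distinct features (partial Fisher-Yates)
      for (int i = 0; i < p; ++i) featPool[i] = i;
      int bestF = -1;
      double bestCut = 0.0, bestGain = -1.0;
      for (int k = 0; k < mtry; ++k) {
        std::uniform_int_distribution<int> pick(k, p - 1);
        int j = pick(rng);
        std::swap(featPool[k], featPool[j]);
        int f = featPool[k];
        double mn = R_PosInf, mx = R_NegInf;
        for (int i = 0; i < m; ++i) {
          double v = X(idx[i], f);
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
        if (!(mx > mn)) continue;
        double cut = mn + (mx - mn) * unif(rng);
        if (cut <= mn || cut >= mx)  // guard against fp edge cases
          cut = (mn + mx) / 2.0;
        double sumL = 0.0; int nL = 0;
        for (int i = 0; i < m; ++i) {
          if (X(idx[i], f) < cut) { sumL += y[idx[i]]; ++nL; }
        }
        if (nL == 0 || nL == m) continue;
        double sumR = sum - sumL;
        int nR = m - nL;
        double gain = sumL * sumL / nL + sumR * sumR / nR -
                      sum * sum / m;
        if (gain > bestGain) {
          bestGain = gain; bestF = f; bestCut = cut;
        }
      }
      if (bestF < 0 || bestGain <= 0.0) continue;
      imp[bestF] += bestGain;
      NodeJob left, right;
      left.idx.reserve(m); right.idx.reserve(m);
      for (int i = 0; i < m; ++i) {
        if (X(idx[i], bestF) < bestCut) left.idx.push_back(idx[i]);
        else right.idx.push_back(idx[i]);
      }
      stack.push_back(std::move(left));
      stack.push_back(std::move(right));
    }
  }
  for (int f = 0; f < p; ++f) imp[f] /= nTrees;
  return imp;
}
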