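// UPGMA (unweighted pair-group average linkage) merge engine and the
// multiscale-bootstrap resampling loop. Merge height = average distance / 2.
// Ties are broken in favour of the pair whose (smallest member, smallest
// member) index pair is lexicographically least; the R wrapper presents taxa
// in sorted-label order so this matches label order. Cluster memberships are
// returned as 64-bit masks (held exactly in doubles for <= 52 taxa).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

namespace {

struct UpgmaOut {
  std::vector<int> m1, m2;        // hclust-style merge codes
  std::vector<double> height;     // merge distance / 2
  std::vector<uint64_t> mask;     // member mask per merge
};

void upgma_run(std::vector<double>& D, int n, UpgmaOut& out) {
  std::vector<int> active(n), code(n), minmem(n), size(n, 1);
  std::vector<uint64_t> mask(n);
  for (int i = 0; i < n; ++i) {
    active[i] = i;
    code[i] = -(i + 1);
    minmem[i] = i;
    mask[i] = 1ULL << i;
  }
  out.m1.clear(); out.m2.clear(); out.height.clear(); out.mask.clear();
  for (int step = 1; step < n; ++step) {
    int na = (int)active.size();
    double dmin = R_PosInf;
    int bi = -1, bj = -1;
    for (int a = 0; a < na; ++a)
      for (int b = a + 1; b < na; ++b) {
        int i = active[a], j = active[b];
        double d = D[(size_t)i * n + j];
        int lo = std::min(minmem[i], minmem[j]);
        int hi = std::max(minmem[i], minmem[j]);
        if (d < dmin ||
            (d == dmin &&
             (lo < std::min(minmem[bi], minmem[bj]) ||
              (lo == std::min(minmem[bi], minmem[bj]) &&
               hi < std::max(minmem[bi], minmem[bj]))))) {
          dmin = d; bi = i; bj = j;
        }
      }
    // UPGMA update: size-weighted average distance to the merged cluster
    for (int k : active) {
      if (k == bi || k == bj) continue;
      double d = (size[bi] * D[(size_t)bi * n + k] +
                  size[bj] * D[(size_t)bj * n + k]) /
                 (size[bi] + size[bj]);
      D[(size_t)bi * n + k] = D[(size_t)k * n + bi] = d;
    }
    out.m1.push_back(std::min(code[bi], code[bj]));
    out.m2.push_back(std::max(code[bi], code[bj]));
    out.height.push_back(dmin / 2.0);
    mask[bi] |= mask[bj];
    out.mask.push_back(mask[bi]);
    code[bi] = step;
    size[bi] += size[bj];
    minmem[bi] = std::min(minmem[bi], minmem[bj]);
    for (size_t a = 0; a < active.size(); ++a)
      if (active[a] == bj) { active.erase(active.begin() + a); break; }
  }
}

void euclid(const std::vector<double>& x, int n, int m,
            std::vector<double>& D) {
  for (int i = 0; i < n; ++i) {
    D[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < m; ++c) {
        double d = x[(size_t)c * n + i] - x[(size_t)c * n + j];
        s += d * d;
      }
      D[(size_t)i * n + j] = D[(size_t)j * n + i] = std::sqrt(s);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".upgma_cpp")]]
List upgma_cpp(NumericMatrix d) {
  int n = d.nrow();
  if (n < 2) stop("UPGMA needs at least 2 taxa");
  if (n > 52) stop("at most 52 taxa supported");
  std::vector<double> D(d.begin(), d.end());
  UpgmaOut out;
  upgma_run(D, n, out);
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1), mask(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    merge(i, 0) = out.m1[i];
    merge(i, 1) = out.m2[i];
    height[i] = out.height[i];
    mask[i] = (double)out.mask[i];
  }
  return List::create(_["merge"] = merge, _["height"] = height,
                      _["mask"] = mask);
}

// [[Rcpp::export(name = ".boot_counts_cpp")]]
List boot_counts_cpp(NumericMatrix x, NumericVector scales, int n_boot,
                     NumericVector obs_masks, bool restandardize) {
  int n = x.nrow(), m = x.ncol();
  int S = scales.size(), K = obs_masks.size();
  if (n > 52) stop("at most 52 taxa supported");
  std::vector<uint64_t> obs(K);
  for (int k = 0; k < K; ++k) obs[k] = (uint64_t)obs_masks[k];
  IntegerMatrix counts(K, S);
  IntegerVector usable(S);
  std::vector<double> xb, D((size_t)n * n);
  UpgmaOut out;
  for (int s = 0; s < S; ++s) {
    int m2 = std::max(1, (int)std::lround(scales[s] * m));
    xb.assign((size_t)n * m2, 0.0);
    for (int b = 0; b < n_boot; ++b) {
      for (int c = 0; c < m2; ++c) {
        int col = (int)(unif_rand() * m);
        if (col >= m) col = m - 1;
        for (int i = 0; i < n; ++i)
          xb[(size_t)c * n + i] = x[(size_t)col * n + i];
      }
      if (restandardize) {
        for (int c = 0; c < m2; ++c) {
          double mu = 0, ss = 0;
          for (int i = 0; i < n; ++i) mu += xb[(size_t)c * n + i];
          mu /= n;
          for (int i = 0; i < n; ++i) {
            double dd = xb[(size_t)c * n + i] - mu;
            ss += dd * dd;
          }
          double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
          for (int i = 0; i < n; ++i)
            xb[(size_t)c * n + i] = (sd > 0)
              ? (xb[(size_t)c * n + i] - mu) / sd : 0.0;
        }
      }
      euclid(xb, n, m2, D);
      double dmax = 0;
      for (size_t t = 0; t < D.size(); ++t) if (D[t] > dmax) dmax = D[t];
      if (dmax <= 0) continue;                  // degenerate resample
      usable[s] += 1;
      upgma_run(D, n, out);
      std::unordered_set<uint64_t> seen(out.mask.begin(), out.mask.end());
      for (int k = 0; k < K; ++k)
        if (seen.count(obs[k])) counts(k, s) += 1;
    }
  }
  return List::create(_["counts"] = counts, _["usable"] = usable);
}
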