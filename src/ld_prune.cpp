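// Sliding-window LD pruning. Pairwise r^2 is the squared Pearson
// correlation of additive dosages over pairwise-complete samples; a
// zero-variance (monomorphic) SNP has r^2 = 0 against everything.

#include <Rcpp.h>
using namespace Rcpp;

static double pair_r2(const double* a, const double* b, int n) {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double x = a[i], y = b[i];
    if (ISNAN(x) || ISNAN(y)) continue;
    sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
    ++cnt;
  }
  if (cnt < 2) return 0.0;
  double vx = cnt * sxx - sx * sx;
  double vy = cnt * syy - sy * sy;
  if (vx <= 0 || vy <= 0) return 0.0;
  double cov = cnt * sxy - sx * sy;
  return (cov * cov) / (vx * vy);
}

// [[Rcpp::export]]
LogicalVector ld_prune_cpp(const NumericMatrix& G, int window_snps,
                           int step_snps, double r2_max) {
  const int n = G.nrow(), m = G.ncol();
  LogicalVector keep(m, true);
  if (m < 2) return keep;
  const double* base = REAL(G);
  int prev_end = -1;
  for (int start = 0; start < m; start += step_snps) {
    int end = std::min(start + window_snps - 1, m - 1);
    // Scanning pairs in genomic order; removing the later SNP of a violating
    // pair cannot create new violations among earlier pairs, so one ordered
    // pass reaches the fixed point. Pairs wholly inside the previous window
    // were already resolved (r^2 is fixed; removals persist), so only pairs
    // whose later SNP entered with this window need checking.
    for (int j = std::max(start + 1, prev_end + 1); j <= end; ++j) {
      if (!keep[j]) continue;
      for (int i = start; i < j; ++i) {
        if (!keep[i]) continue;
        if (pair_r2(base + (size_t)i * n, base + (size_t)j * n, n) > r2_max) {
          keep[j] = false;
          break;
        }
      }
    }
    prev_end = end;
    if (end == m - 1) break;
  }
  return keep;
}
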