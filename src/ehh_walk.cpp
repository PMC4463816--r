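#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Extended-haplotype-homozygosity walk outward from a core SNP.
//
// Among the given haplotype rows, EHH at marker x is the probability that
// two randomly chosen haplotypes are identical over all visited markers
// from the first step beyond the core through x:
//   EHH(x) = sum_g C(c_g, 2) / C(n, 2)
// over the distinct extended haplotypes g with counts c_g. The walk visits
// successive markers in one direction and stops at the first marker with
// EHH < cutoff (that marker is included in the output), at the chromosome
// bounds, or *before* a physical gap larger than gap_max.
//
// haps: H x M 0/1 matrix; rows: 0-based carrier row indices; core: 0-based
// core column; step: +1 (right) / -1 (left); lo/hi: inclusive 0-based column
// bounds of the core's chromosome; pos: physical positions (bp).
// Returns 0-based marker columns, EHH values, and a stop reason:
// 0 = cutoff reached, 1 = chromosome bound, 2 = gap.
// [[Rcpp::export]]
List ehh_walk_cpp(const IntegerMatrix& haps, const IntegerVector& rows,
                  int core, int step, int lo, int hi,
                  const NumericVector& pos, double cutoff, double gap_max) {
  const int n = rows.size();
  if (n < 2) stop("ehh_walk_cpp: need at least 2 haplotypes");
  std::vector<int> grp(n, 0);
  std::vector<int> cols;
  std::vector<double> vals;
  int reason = 1;
  const double denom = (double)n * (n - 1) / 2.0;
  int prev = core;
  for (int j = core + step; j >= lo && j <= hi; j += step) {
    if (std::fabs(pos[j] - pos[prev]) > gap_max) { reason = 2; break; }
    std::unordered_map<long long, int> remap;
    remap.reserve(2 * n);
    std::vector<int> cnt;
    int next_id = 0;
    for (int i = 0; i < n; ++i) {
      long long key = (long long)grp[i] * 2 + haps(rows[i], j);
      auto it = remap.find(key);
      int id;
      if (it == remap.end()) {
        id = next_id++;
        remap.emplace(key, id);
        cnt.push_back(0);
      } else {
        id = it->second;
      }
      grp[i] = id;
      cnt[id]++;
    }
    double s = 0.0;
    for (int c : cnt) s += (double)c * (c - 1) / 2.0;
    double e = s / denom;
    cols.push_back(j);
    vals.push_back(e);
    prev = j;
    if (e < cutoff) { reason = 0; break; }
  }
  return List::create(_["col"] = wrap(cols), _["ehh"] = wrap(vals),
                      _["reason"] = reason);
}
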