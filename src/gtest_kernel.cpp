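#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// G statistic for a 3x3 contingency table held as cnt[row*3+col].
// All-zero rows/columns are deleted before computing df; a table with fewer
// than 2 non-empty rows or columns is uninformative. Optionally applies
// Williams' small-sample correction (G / q) before the chi-square tail.
static inline double gstat9(const int *cnt, int n, int &df, bool &informative,
                            bool williams) {
  int rs[3] = {0, 0, 0}, cs[3] = {0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      rs[i] += cnt[3 * i + j];
      cs[j] += cnt[3 * i + j];
    }
  int nr = 0, nc = 0;
  for (int i = 0; i < 3; ++i) {
    if (rs[i] > 0) ++nr;
    if (cs[i] > 0) ++nc;
  }
  if (nr < 2 || nc < 2) {
    informative = false;
    df = 0;
    return 0.0;
  }
  informative = true;
  df = (nr - 1) * (nc - 1);
  double g = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      int o = cnt[3 * i + j];
      if (o > 0) {
        double e = (double)rs[i] * (double)cs[j] / (double)n;
        g += (double)o * std::log((double)o / e);
      }
    }
  g *= 2.0;
  if (williams) {
    double sr = 0.0, sc = 0.0;
    for (int i = 0; i < 3; ++i) {
      if (rs[i] > 0) sr += 1.0 / (double)rs[i];
      if (cs[i] > 0) sc += 1.0 / (double)cs[i];
    }
    double q = 1.0 + ((double)n * sr - 1.0) * ((double)n * sc - 1.0) /
                         (6.0 * (double)n * (double)df);
    g /= q;
  }
  return g;
}

// [[Rcpp::export(name = ".gtest_pair_cpp")]]
NumericVector gtest_pair_cpp(IntegerVector a, IntegerVector b,
                             bool williams = false) {
  int n = a.size();
  int cnt[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (int s = 0; s < n; ++s) cnt[a[s] * 3 + b[s]] += 1;
  int df;
  bool informative;
  double g = gstat9(cnt, n, df, informative, williams);
  double p = informative ? R::pchisq(g, (double)df, 0, 0) : 1.0;
  return NumericVector::create(g, (double)df, p, informative ? 1.0 : 0.0);
}

// Bootstrap edge-inclusion frequencies.
//   levels : genes x samples integer matrix with entries in {0,1,2}
//   pairs  : P x 2 matrix of 0-based gene row indices
//   boot   : n x R matrix of 0-based sample column indices (one size-preserved
//            with-replacement resample per column; fully seeded upstream)
//   alpha  : per-pair inclusion significance level
// Each resample's pair tests run on the DISTINCT samples of the draw with
// Williams' correction: duplicated bootstrap rows carry no independent
// evidence and would otherwise inflate the G-test far beyond its nominal
// level. Returns, per pair, the fraction of resamples in which independence
// was rejected at that pair's alpha; uninformative tables never reject.
// [[Rcpp::export(name = ".boot_edge_freq_cpp")]]
NumericVector boot_edge_freq_cpp(IntegerMatrix levels, IntegerMatrix pairs,
                                 IntegerMatrix boot, NumericVector alpha) {
  int P = pairs.nrow(), n = boot.nrow(), R = boot.ncol();
  int n_all = levels.ncol();
  NumericVector freq(P);
  std::vector<int> hits(P, 0);
  std::vector<int> uniq;
  uniq.reserve(n);
  std::vector<char> seen(n_all);
  for (int r = 0; r < R; ++r) {
    uniq.clear();
    std::fill(seen.begin(), seen.end(), 0);
    for (int s = 0; s < n; ++s) {
      int col = boot(s, r);
      if (!seen[col]) {
        seen[col] = 1;
        uniq.push_back(col);
      }
    }
    int m = (int)uniq.size();
    for (int p = 0; p < P; ++p) {
      int ga = pairs(p, 0), gb = pairs(p, 1);
      int cnt[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (int s = 0; s < m; ++s) {
        int col = uniq[s];
        cnt[levels(ga, col) * 3 + levels(gb, col)] += 1;
      }
      int df;
      bool informative;
      double g = gstat9(cnt, m, df, informative, true);
      if (informative && R::pchisq(g, (double)df, 0, 0) < alpha[p]) hits[p] += 1;
    }
  }
  for (int p = 0; p < P; ++p) freq[p] = (double)hits[p] / (double)R;
  return freq;
}
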