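#include <Rcpp.h>
using namespace Rcpp;

// Base coding: A=0 C=1 G=2 T=3 N=4 (see DNA_CODE in R/triplet-tables.R).
//
// scan_triplexes_cpp enumerates every (anchor, stem length, loop1, loop2)
// tuple of one class on one already-oriented strand. The triad at stack
// position k of a candidate with stemA at [p, p+L) is
//   (seq[p+k], seq[bs + L-1-k], seq[cs + k])
// with bs = p + L + l1 and cs = bs + L + l2; a candidate qualifies when the
// number of stack positions whose triad is not in the class's triad set is
// at most the allowance (0 for L == 6, 1 for L >= 7 when mismatches are on).
// A run-length prefilter on the stemA alphabet (off-alphabet letters are
// counted; they can never form a valid triad, so off > allowance disqualifies
// every candidate anchored there) keeps the scan near-linear on genomes.

static inline int allowance(int L, bool mism) {
  return (mism && L >= 7) ? 1 : 0;
}

// [[Rcpp::export]]
DataFrame scan_triplexes_cpp(IntegerVector seq, LogicalVector valid,
                             int cls, int min_stem, int max_stem,
                             int min_loop, int max_loop, bool mismatch,
                             int limit_start) {
  const int n = seq.size();
  // valid is the 4x5x5x5 array from triad_lookup(); index (cls-1, a, b, c)
  auto ok = [&](int a, int b, int c) -> bool {
    return valid[(cls - 1) + 4 * (a + 5 * (b + 5 * c))];
  };
  // stemA alphabet of the class: letters that occur as `a` in some triad
  bool alpha[5] = {false, false, false, false, false};
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      for (int c = 0; c < 5; ++c)
        if (ok(a, b, c)) alpha[a] = true;
  // prefix sums of off-alphabet letters
  std::vector<int> offcum(n + 1, 0);
  for (int i = 0; i < n; ++i)
    offcum[i + 1] = offcum[i] + (alpha[seq[i]] ? 0 : 1);

  std::vector<int> r_start, r_stem, r_l1, r_l2, r_mm;
  for (int p = 0; p < limit_start; ++p) {
    for (int L = min_stem; L <= max_stem; ++L) {
      if (p + L > n) break;
      int allow = allowance(L, mismatch);
      if (offcum[p + L] - offcum[p] > allow) continue;
      for (int l1 = min_loop; l1 <= max_loop; ++l1) {
        int bs = p + L + l1;
        if (bs + L > n) break;
        for (int l2 = min_loop; l2 <= max_loop; ++l2) {
          int cs = bs + L + l2;
          if (cs + L > n) break;
          int mm = 0;
          for (int k = 0; k < L; ++k) {
            if (!ok(seq[p + k], seq[bs + L - 1 - k], seq[cs + k])) {
              if (++mm > allow) break;
            }
          }
          if (mm <= allow) {
            r_start.push_back(p);
            r_stem.push_back(L);
            r_l1.push_back(l1);
            r_l2.push_back(l2);
            r_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["start0"] = r_start, _["stem_len"] = r_stem,
                           _["loop1_len"] = r_l1, _["loop2_len"] = r_l2,
                           _["mismatches"] = r_mm);
}

// Hairpin scan: two arms of a perfect (up to max_mismatch) inverted repeat.
// Arm1 at [p, p+L), loop of length l, arm2 at [p+L+l, p+2L+l); position k of
// arm1 must Watson-Crick pair arm2[L-1-k]. N pairs nothing.
// [[Rcpp::export]]
DataFrame scan_hairpins_cpp(IntegerVector seq, int min_stem, int max_stem,
                            int min_loop, int max_loop, int max_mismatch,
                            int limit_start) {
  const int n = seq.size();
  auto pairs = [](int a, int b) -> bool {
    return (a == 0 && b == 3) || (a == 3 && b == 0) ||
           (a == 1 && b == 2) || (a == 2 && b == 1);
  };
  std::vector<int> r_start, r_stem, r_loop, r_mm;
  for (int p = 0; p < limit_start; ++p) {
    for (int L = min_stem; L <= max_stem; ++L) {
      for (int l = min_loop; l <= max_loop; ++l) {
        int a2 = p + L + l;
        if (a2 + L > n) break;
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (!pairs(seq[p + k], seq[a2 + L - 1 - k])) {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm <= max_mismatch) {
          r_start.push_back(p);
          r_stem.push_back(L);
          r_loop.push_back(l);
          r_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["start0"] = r_start, _["stem_len"] = r_stem,
                           _["loop_len"] = r_loop, _["mismatches"] = r_mm);
}
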