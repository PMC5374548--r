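#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cstdlib>
using namespace Rcpp;

// Banded Levenshtein with an abandonment cap: returns the exact distance when
// it is <= cap, and any value > cap otherwise. Cells outside the |i-j| <= cap
// band cannot lie on a path of cost <= cap, so they are treated as infinite.
static int lev_capped(const char* a, int la, const char* b, int lb, int cap) {
  int maxlen = la > lb ? la : lb;
  if (cap > maxlen) cap = maxlen;
  if (la == 0) return lb;
  if (lb == 0) return la;
  if (std::abs(la - lb) > cap) return cap + 1;
  const int BIG = cap + 1;
  std::vector<int> prev(lb + 2), cur(lb + 2);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= cap) ? j : BIG;
  for (int i = 1; i <= la; ++i) {
    int jlo = i - cap; if (jlo < 1) jlo = 1;
    int jhi = i + cap; if (jhi > lb) jhi = lb;
    cur[jlo - 1] = (jlo == 1) ? ((i <= cap) ? i : BIG) : BIG;
    int rowmin = BIG;
    for (int j = jlo; j <= jhi; ++j) {
      int v = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      if (del < v) v = del;
      if (ins < v) v = ins;
      if (v > BIG) v = BIG;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (jhi < lb) cur[jhi + 1] = BIG;  // guard for next row's band edge
    if (rowmin > cap) return BIG;
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export]]
IntegerVector lev_capped_cpp(CharacterVector a, CharacterVector b, int cap) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, i % a.size()));
    const char* sb = CHAR(STRING_ELT(b, i % b.size()));
    out[i] = lev_capped(sa, (int) std::strlen(sa), sb, (int) std::strlen(sb), cap);
  }
  return out;
}

// Exhaustive offset scan: place c2 (reverse complement of R2) at every offset
// O under r1, compute the edit distance of the vertically aligned slices, and
// keep the offset with minimal distance; ties broken toward larger overlap,
// then smaller |O|, then positive O. Offsets are visited in tie-preference
// order for |O|/sign so a strictly better candidate is required to replace.
// [[Rcpp::export]]
List overlap_scan_cpp(CharacterVector r1, CharacterVector c2, int min_overlap) {
  int n = r1.size();
  if (c2.size() != n) stop("r1 and c2 must have equal length");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  IntegerVector off(n), olen(n), ed(n);
  for (int p = 0; p < n; ++p) {
    const char* a = CHAR(STRING_ELT(r1, p));
    const char* b = CHAR(STRING_ELT(c2, p));
    int la = (int) std::strlen(a), lb = (int) std::strlen(b);
    int omin = -(lb - min_overlap), omax = la - min_overlap;
    int best_ed = -1, best_len = -1, best_off = NA_INTEGER;
    int maxd = std::max(std::abs(omin), std::abs(omax));
    // Hamming prescan: positional mismatches bound the edit distance from
    // above, so the minimum Hamming over offsets caps every DP and lets
    // wrong offsets abandon almost immediately.
    int min_h = INT_MAX;
    for (int O = omin; O <= omax; ++O) {
      int a_start = O > 0 ? O : 0;
      int a_end = std::min(la, O + lb);
      int L = a_end - a_start;
      if (L < 1) continue;
      const char* pa = a + a_start;
      const char* pb = b + (O < 0 ? -O : 0);
      int h = 0;
      for (int t = 0; t < L && h < min_h; ++t) h += (pa[t] != pb[t]);
      if (h < min_h) min_h = h;
    }
    for (int d = 0; d <= maxd; ++d) {
      for (int s = 0; s < (d == 0 ? 1 : 2); ++s) {
        int O = (s == 0) ? d : -d;
        if (O < omin || O > omax) continue;
        int a_start = O > 0 ? O : 0;
        int a_end = std::min(la, O + lb);
        int L = a_end - a_start;
        if (L < 1) continue;
        int b_start = O < 0 ? -O : 0;
        int cap = (best_ed < 0) ? L : best_ed;
        if (min_h < cap) cap = min_h;  // true optimum is <= min_h
        int e = lev_capped(a + a_start, L, b + b_start, L, cap);
        bool better = (best_ed < 0) || (e < best_ed) ||
          (e == best_ed && L > best_len);
        if (better) { best_ed = e; best_len = L; best_off = O; }
      }
    }
    if (best_ed < 0) { off[p] = NA_INTEGER; olen[p] = 0; ed[p] = NA_INTEGER; }
    else { off[p] = best_off; olen[p] = best_len; ed[p] = best_ed; }
  }
  return List::create(_["offset"] = off, _["overlap_len"] = olen,
                      _["edit_dist"] = ed);
}

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return 4;
  }
}

// Per-cycle base counts (A,C,G,T,N columns) and quality sums.
// [[Rcpp::export]]
List cycle_profile_cpp(CharacterVector bases, CharacterVector quals) {
  int n = bases.size();
  if (quals.size() != n) stop("bases and quals must have equal length");
  int maxlen = 0;
  for (int i = 0; i < n; ++i) {
    int l = (int) std::strlen(CHAR(STRING_ELT(bases, i)));
    if (l > maxlen) maxlen = l;
  }
  IntegerMatrix counts(maxlen > 0 ? maxlen : 0, 5);
  NumericVector qualsum(maxlen > 0 ? maxlen : 0);
  IntegerVector total(maxlen > 0 ? maxlen : 0);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(bases, i));
    const char* q = CHAR(STRING_ELT(quals, i));
    int l = (int) std::strlen(s);
    if ((int) std::strlen(q) != l) stop("read %d: bases/quals length mismatch", i + 1);
    for (int c = 0; c < l; ++c) {
      counts(c, base_idx(s[c]))++;
      qualsum[c] += (double) (q[c] - 33);
      total[c]++;
    }
  }
  return List::create(_["counts"] = counts, _["qual_sum"] = qualsum,
                      _["total"] = total);
}

// Per-read N count, low-quality-base count and mean Phred score.
// [[Rcpp::export]]
List read_qual_stats_cpp(CharacterVector bases, CharacterVector quals,
                         int low_thresh) {
  int n = bases.size();
  IntegerVector nN(n), nlow(n);
  NumericVector meanq(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(bases, i));
    const char* q = CHAR(STRING_ELT(quals, i));
    int l = (int) std::strlen(s);
    int cn = 0, cl = 0; double sq = 0;
    for (int c = 0; c < l; ++c) {
      if (s[c] == 'N') cn++;
      int ph = q[c] - 33;
      if (ph < low_thresh) cl++;
      sq += ph;
    }
    nN[i] = cn; nlow[i] = cl;
    meanq[i] = l > 0 ? sq / l : 0.0;
  }
  return List::create(_["n_count"] = nN, _["low_count"] = nlow,
                      _["mean_qual"] = meanq);
}
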