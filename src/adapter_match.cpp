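#include <Rcpp.h>
#include <cstring>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Error-tolerant semi-global adapter matching under unit-cost edits.
//
// A candidate alignment aligns a contiguous piece of the adapter (the full
// adapter for internal hits; a prefix reaching the read's 3' end in BACK
// mode; a suffix anchored at the read's 5' start in FRONT mode) against a
// read segment [start, end).  Admissible iff
//   errors <= floor(error_rate * adapter_bases_aligned)  and
//   adapter_bases_aligned >= min_overlap.
// Best = fewest errors, then most adapter bases aligned, then smallest
// start, then smallest end.  'N' never matches anything.

struct Cand {
  int errors, aligned, start, end;
};

static inline bool better(const Cand &a, const Cand &b) {
  if (a.errors != b.errors) return a.errors < b.errors;
  if (a.aligned != b.aligned) return a.aligned > b.aligned;
  if (a.start != b.start) return a.start < b.start;
  return a.end < b.end;
}

static inline bool base_match(char a, char r) { return a == r && a != 'N'; }

static inline int max_errors(double error_rate, int aligned) {
  return (int)std::floor(error_rate * (double)aligned + 1e-9);
}

struct Best {
  Cand c;
  bool found;
  double error_rate;
  int min_overlap;
  Best(double er, int mo) : found(false), error_rate(er), min_overlap(mo) {
    c = {INT_MAX, -1, -1, -1};
  }
  void consider(int errors, int aligned, int start, int end) {
    if (aligned < min_overlap) return;
    if (errors > max_errors(error_rate, aligned)) return;
    Cand cand = {errors, aligned, start, end};
    if (!found || better(cand, c)) { c = cand; found = true; }
  }
};

// Semi-global DP of adapter `ad` against `read` with a free alignment start
// in the read.  Cell (i, j) holds the minimal edit cost of aligning
// ad[0..i) against read[s..j) over all s <= j, plus the start s achieving
// it (ties by smallest s when prefer_max_start is false, largest s
// otherwise).  Row i == m yields full-adapter candidates; rows i < m at
// column n yield adapter-prefix candidates ending at the read's 3' end.
//
// emit_full / emit_prefix select which candidate families to report through
// `cb`; the FRONT machinery reuses this routine on reversed strings.
template <typename Emit>
static void semiglobal_scan(const char *read, int n, const char *ad, int m,
                            bool emit_full, bool emit_prefix,
                            bool prefer_max_start, Emit cb) {
  std::vector<int> D(n + 1), S(n + 1), Dp(n + 1), Sp(n + 1);
  for (int j = 0; j <= n; ++j) { Dp[j] = 0; Sp[j] = j; }
  for (int i = 1; i <= m; ++i) {
    D[0] = i; S[0] = 0;
    const char a = ad[i - 1];
    for (int j = 1; j <= n; ++j) {
      int c = Dp[j - 1] + (base_match(a, read[j - 1]) ? 0 : 1);
      int s = Sp[j - 1];
      int cu = Dp[j] + 1, su = Sp[j];          // gap in read (deletion)
      if (cu < c || (cu == c && (prefer_max_start ? su > s : su < s))) {
        c = cu; s = su;
      }
      int cl = D[j - 1] + 1, sl = S[j - 1];     // gap in adapter (insertion)
      if (cl < c || (cl == c && (prefer_max_start ? sl > s : sl < s))) {
        c = cl; s = sl;
      }
      D[j] = c; S[j] = s;
    }
    if (i == m) {
      if (emit_full)
        for (int j = 0; j <= n; ++j) cb(D[j], m, S[j], j, true);
    } else if (emit_prefix) {
      cb(D[n], i, S[n], n, false);
    }
    std::swap(D, Dp); std::swap(S, Sp);
  }
}

// mode: 1 = BACK (3' adapter, "-a"), 2 = FRONT (5' adapter, "-g"),
//       3 = ANYWHERE ("-b").
static Cand find_best(const std::string &read, const std::string &ad,
                      int mode, double error_rate, int min_overlap,
                      bool &found) {
  const int n = (int)read.size(), m = (int)ad.size();
  Best best(error_rate, min_overlap);
  // Full-adapter-anywhere candidates (all modes) and, for BACK/ANYWHERE,
  // adapter prefixes reaching the read's 3' end.
  semiglobal_scan(read.c_str(), n, ad.c_str(), m,
                  true, mode != 2, false,
                  [&](int errors, int aligned, int start, int end, bool) {
                    best.consider(errors, aligned, start, end);
                  });
  if (mode != 1) {
    // Adapter suffixes anchored at the read's 5' start: scan reversed
    // strings; a prefix of rev(ad) ending at rev(read)'s 3' end maps to a
    // suffix of ad starting at read position 0.  Tracking the largest
    // reversed start yields the smallest original end.
    std::string rr(read.rbegin(), read.rend()), ra(ad.rbegin(), ad.rend());
    // spans rev positions [S, n) map to original [0, n - S)
    semiglobal_scan(rr.c_str(), n, ra.c_str(), m,
                    false, true, true,
                    [&](int errors, int aligned, int start, int end, bool) {
                      (void)end;
                      best.consider(errors, aligned, 0, n - start);
                    });
  }
  found = best.found;
  return best.c;
}

// [[Rcpp::export]]
IntegerMatrix cpp_match_adapter(CharacterVector reads, std::string adapter,
                                int mode, double error_rate,
                                int min_overlap) {
  const int nr = reads.size();
  IntegerMatrix out(nr, 5);
  colnames(out) = CharacterVector::create("start", "end", "aligned",
                                          "errors", "matched");
  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    bool found = false;
    Cand c = find_best(read, adapter, mode, error_rate, min_overlap, found);
    if (found) {
      out(r, 0) = c.start; out(r, 1) = c.end;
      out(r, 2) = c.aligned; out(r, 3) = c.errors; out(r, 4) = 1;
    } else {
      out(r, 0) = NA_INTEGER; out(r, 1) = NA_INTEGER;
      out(r, 2) = NA_INTEGER; out(r, 3) = NA_INTEGER; out(r, 4) = 0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force reference: exhaustively enumerates every (start, end, adapter
// span) candidate with plain anchored edit-distance DPs, then applies the
// same admissibility rule and comparator.  Independent of the semi-global
// start-tracking search above; used as the in-repo ground truth.

// edit distance table of `a` (rows) vs read[s..n), returning, for each
// column j, the distance of a against read[s..s+j).
static void anchored_dp(const char *a, int la, const char *r, int lr,
                        std::vector<std::vector<int> > &T) {
  T.assign(la + 1, std::vector<int>(lr + 1, 0));
  for (int j = 0; j <= lr; ++j) T[0][j] = j;
  for (int i = 1; i <= la; ++i) {
    T[i][0] = i;
    for (int j = 1; j <= lr; ++j) {
      int c = T[i - 1][j - 1] + (base_match(a[i - 1], r[j - 1]) ? 0 : 1);
      c = std::min(c, T[i - 1][j] + 1);
      c = std::min(c, T[i][j - 1] + 1);
      T[i][j] = c;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_match_adapter_oracle(CharacterVector reads,
                                       std::string adapter, int mode,
                                       double error_rate, int min_overlap) {
  const int nr = reads.size();
  const int m = (int)adapter.size();
  IntegerMatrix out(nr, 5);
  colnames(out) = CharacterVector::create("start", "end", "aligned",
                                          "errors", "matched");
  std::vector<std::vector<int> > T;
  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = (int)read.size();
    Best best(error_rate, min_overlap);
    for (int s = 0; s <= n; ++s) {
      anchored_dp(adapter.c_str(), m, read.c_str() + s, n - s, T);
      for (int e = s; e <= n; ++e)        // full adapter, any start/end
        best.consider(T[m][e - s], m, s, e);
      if (mode != 2)                       // adapter prefix at read 3' end
        for (int i = 1; i < m; ++i)
          best.consider(T[i][n - s], i, s, n);
    }
    if (mode != 1) {                       // adapter suffix at read 5' start
      for (int i = 1; i < m; ++i) {
        anchored_dp(adapter.c_str() + (m - i), i, read.c_str(), n, T);
        for (int e = 0; e <= n; ++e)
          best.consider(T[i][e], i, 0, e);
      }
    }
    if (best.found) {
      out(r, 0) = best.c.start; out(r, 1) = best.c.end;
      out(r, 2) = best.c.aligned; out(r, 3) = best.c.errors; out(r, 4) = 1;
    } else {
      out(r, 0) = NA_INTEGER; out(r, 1) = NA_INTEGER;
      out(r, 2) = NA_INTEGER; out(r, 3) = NA_INTEGER; out(r, 4) = 0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3' quality trimming (BWA-style partial-sum rule): cut at the position
// minimising the running sum of (qual - threshold) accumulated from the 3'
// end; ties keep the longest read.  Qualities are Phred+33 strings.

// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector quals, int threshold) {
  const int nr = quals.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char *q = CHAR(STRING_ELT(quals, r));
    const int L = (int)std::strlen(q);
    long s = 0, best = 0;
    int bestk = L;
    for (int k = L - 1; k >= 0; --k) {
      s += (long)(q[k] - 33) - threshold;
      if (s < best) { best = s; bestk = k; }
    }
    out[r] = bestk;
  }
  return out;
}
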