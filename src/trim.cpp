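#include <Rcpp.h>
using namespace Rcpp;

static inline double window_mean(const std::string &q, int start, int w) {
  const int len = (int)q.size();
  int end = std::min(start + w, len);
  if (end <= start) return 0.0;
  long sum = 0;
  for (int i = start; i < end; ++i) sum += (unsigned char)q[i] - 33;
  return (double)sum / (double)(end - start);
}

// Sliding-window quality cut. Returns a 2-column matrix of kept [start, end)
// 0-based half-open ranges per read.
//   mode 0 (front): drop 5' bases before the first window with mean >= mean_q
//   mode 1 (tail):  drop 3' bases after the last window (ending at j) with
//                   mean >= mean_q
//   mode 2 (right): truncate from the start of the first window with
//                   mean < mean_q onward
// [[Rcpp::export]]
IntegerMatrix cpp_window_cut(CharacterVector qual, int mode, int window,
                             double mean_q) {
  const R_xlen_t n = qual.size();
  IntegerMatrix keep(n, 2);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string q = as<std::string>(qual[r]);
    const int len = (int)q.size();
    int start = 0, end = len;
    if (mode == 0) {
      start = len; // empty unless a qualifying window exists
      for (int i = 0; i < len; ++i) {
        if (window_mean(q, i, window) >= mean_q) { start = i; break; }
      }
    } else if (mode == 1) {
      end = 0;
      for (int j = len - 1; j >= 0; --j) {
        int ws = std::max(0, j - window + 1);
        long sum = 0;
        for (int i = ws; i <= j; ++i) sum += (unsigned char)q[i] - 33;
        if ((double)sum / (double)(j - ws + 1) >= mean_q) { end = j + 1; break; }
      }
    } else {
      for (int i = 0; i < len; ++i) {
        if (window_mean(q, i, window) < mean_q) { end = i; break; }
      }
    }
    if (end < start) end = start;
    keep(r, 0) = start;
    keep(r, 1) = end;
  }
  return keep;
}

static int polyx_run_from_tail(const std::string &s, char target,
                               bool allow_mismatch) {
  const int len = (int)s.size();
  int best = 0, mm = 0;
  for (int k = 1; k <= len; ++k) {
    char c = s[len - k];
    if (c != target) {
      if (!allow_mismatch) break;
      ++mm;
    }
    // run of length k is valid if mismatches fit the 1-per-8-bases budget and
    // the run ends (5'-most base) on a match
    if (c == target && mm <= k / 8) best = k;
    if (mm > k / 8 && mm > len / 8) break; // no longer recoverable
  }
  return best;
}

// trim length from the 3' end for a polyX run of >= min_len bases of `base`
// ('\0' byte given as "" => best over A/C/G/T)
// [[Rcpp::export]]
IntegerVector cpp_polyx_trim(CharacterVector seqs, std::string base,
                             int min_len, bool allow_mismatch) {
  const R_xlen_t n = seqs.size();
  IntegerVector out(n);
  const std::string bases = base.empty() ? "ACGT" : base;
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int best = 0;
    for (char b : bases) {
      int run = polyx_run_from_tail(s, b, allow_mismatch);
      if (run > best) best = run;
    }
    out[r] = best >= min_len ? best : 0;
  }
  return out;
}

// leftmost 0-based position where the adapter prefix matches with at most
// floor(frac * matchlen) mismatches and matchlen >= min_match; -1 if none
// [[Rcpp::export]]
IntegerVector cpp_adapter_find(CharacterVector seqs, std::string adapter,
                               double mismatch_frac, int min_match) {
  const R_xlen_t n = seqs.size();
  const int alen = (int)adapter.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int len = (int)s.size();
    int hit = -1;
    for (int p = 0; p <= len - min_match; ++p) {
      int matchlen = std::min(alen, len - p);
      if (matchlen < min_match) break;
      int budget = (int)std::floor(mismatch_frac * matchlen);
      int mm = 0;
      bool ok = true;
      for (int i = 0; i < matchlen; ++i) {
        if (s[p + i] != adapter[i] && ++mm > budget) { ok = false; break; }
      }
      if (ok) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}

// read filter verdicts: 0 pass, 1 low_quality, 2 too_many_N, 3 too_short,
// 4 too_long; checks applied in that order, first failure wins
// [[Rcpp::export]]
IntegerVector cpp_filter_eval(CharacterVector seqs, CharacterVector quals,
                              int qualified_phred, double max_unq_frac,
                              int max_n, int min_len, int max_len) {
  const R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    const int len = (int)strlen(s);
    int unq = 0, nn = 0;
    for (int i = 0; i < len; ++i) {
      if ((unsigned char)q[i] - 33 < qualified_phred) ++unq;
      if (s[i] == 'N') ++nn;
    }
    int v = 0;
    if (len > 0 && (double)unq / (double)len > max_unq_frac) v = 1;
    else if (nn > max_n) v = 2;
    else if (len < min_len) v = 3;
    else if (max_len > 0 && len > max_len) v = 4;
    out[r] = v;
  }
  return out;
}
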