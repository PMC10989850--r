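#include <Rcpp.h>
#include "seqscrub.h"
using namespace Rcpp;

// Mismatch count between r1 and revcomp(r2) at a given offset o (R1
// coordinates of the first aligned base of revcomp(r2)). Overlap window:
//   o >= 0: r1[o + i] vs s2rc[i],      i in [0, min(len1 - o, len2))
//   o <  0: r1[i]     vs s2rc[i - o],  i in [0, min(len1, len2 + o))
// Early exit once the mismatch budget is exceeded.
static inline int count_mismatches(const std::string &s1, const std::string &s2rc,
                                   int o, int ov, int budget) {
  int mm = 0;
  if (o >= 0) {
    for (int i = 0; i < ov; ++i) {
      if (s1[o + i] != s2rc[i] && ++mm > budget) return mm;
    }
  } else {
    for (int i = 0; i < ov; ++i) {
      if (s1[i] != s2rc[i - o] && ++mm > budget) return mm;
    }
  }
  return mm;
}

static inline int overlap_len_at(int o, int len1, int len2) {
  return o >= 0 ? std::min(len1 - o, len2) : std::min(len1, len2 + o);
}

// [[Rcpp::export]]
List cpp_overlap_analyze(CharacterVector seq1, CharacterVector seq2,
                         int min_overlap, int max_mismatch,
                         double max_mismatch_frac) {
  const R_xlen_t n = seq1.size();
  if (seq2.size() != n) stop("mate vectors differ in length");
  LogicalVector found(n);
  IntegerVector offset(n), ovlen(n), mism(n);
  List mmpos(n);

  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s1 = as<std::string>(seq1[r]);
    std::string s2rc = revcomp_one(as<std::string>(seq2[r]));
    const int len1 = (int)s1.size(), len2 = (int)s2rc.size();
    bool ok = false;
    int best_o = 0, best_ov = 0, best_mm = 0;

    const int max_abs = std::max(len1 - min_overlap, len2 - min_overlap);
    for (int a = 0; a <= max_abs && !ok; ++a) {
      // non-negative offset first at equal |offset|
      for (int sign = 0; sign < 2 && !ok; ++sign) {
        if (a == 0 && sign == 1) continue;
        int o = sign == 0 ? a : -a;
        if (o >= 0 && o > len1 - min_overlap) continue;
        if (o < 0 && -o > len2 - min_overlap) continue;
        int ov = overlap_len_at(o, len1, len2);
        if (ov < min_overlap) continue;
        int budget = std::min(max_mismatch,
                              (int)std::floor(max_mismatch_frac * ov));
        int mm = count_mismatches(s1, s2rc, o, ov, budget);
        if (mm <= budget) {
          ok = true;
          best_o = o;
          best_ov = ov;
          best_mm = mm;
        }
      }
    }
    found[r] = ok;
    offset[r] = ok ? best_o : NA_INTEGER;
    ovlen[r] = ok ? best_ov : 0;
    mism[r] = ok ? best_mm : NA_INTEGER;
    if (ok && best_mm > 0) {
      IntegerVector pos(best_mm);
      int k = 0;
      for (int i = 0; i < best_ov; ++i) {
        int i1 = best_o >= 0 ? best_o + i : i;
        int i2 = best_o >= 0 ? i : i - best_o;
        if (s1[i1] != s2rc[i2]) pos[k++] = i1 + 1; // 1-based R1 coordinate
      }
      mmpos[r] = pos;
    } else {
      mmpos[r] = IntegerVector(0);
    }
  }
  return List::create(_["found"] = found, _["offset"] = offset,
                      _["overlap_len"] = ovlen, _["mismatches"] = mism,
                      _["mismatch_positions"] = mmpos);
}

// [[Rcpp::export]]
List cpp_correct_bases(CharacterVector seq1, CharacterVector qual1,
                       CharacterVector seq2, CharacterVector qual2,
                       LogicalVector found, IntegerVector offset,
                       int high_q, int low_q) {
  const R_xlen_t n = seq1.size();
  CharacterVector o_s1 = clone(seq1), o_q1 = clone(qual1);
  CharacterVector o_s2 = clone(seq2), o_q2 = clone(qual2);
  IntegerVector ncorr(n);

  for (R_xlen_t r = 0; r < n; ++r) {
    if (!found[r]) continue;
    std::string s1 = as<std::string>(seq1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2 = as<std::string>(seq2[r]);
    std::string q2 = as<std::string>(qual2[r]);
    std::string s2rc = revcomp_one(s2);
    const int len1 = (int)s1.size(), len2 = (int)s2.size();
    const int o = offset[r];
    const int ov = overlap_len_at(o, len1, len2);
    int corr = 0;
    for (int i = 0; i < ov; ++i) {
      int i1 = o >= 0 ? o + i : i;         // R1 coordinate
      int i2 = o >= 0 ? i : i - o;         // revcomp(R2) coordinate
      if (s1[i1] == s2rc[i2]) continue;
      int j2 = len2 - 1 - i2;              // original R2 coordinate
      int p1 = (unsigned char)q1[i1] - 33;
      int p2 = (unsigned char)q2[j2] - 33;
      if (p1 >= high_q && p2 < low_q) {
        // overwrite R2 base with the complement of R1's base
        std::string rc1 = revcomp_one(std::string(1, s1[i1]));
        s2[j2] = rc1[0];
        q2[j2] = q1[i1];
        ++corr;
      } else if (p2 >= high_q && p1 < low_q) {
        s1[i1] = s2rc[i2];
        q1[i1] = q2[j2];
        ++corr;
      }
    }
    if (corr > 0) {
      o_s1[r] = s1; o_q1[r] = q1;
      o_s2[r] = s2; o_q2[r] = q2;
    }
    ncorr[r] = corr;
  }
  return List::create(_["seq1"] = o_s1, _["qual1"] = o_q1, _["seq2"] = o_s2,
                      _["qual2"] = o_q2, _["corrected"] = ncorr);
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     LogicalVector found, IntegerVector offset) {
  const R_xlen_t n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector mlen(n);

  for (R_xlen_t r = 0; r < n; ++r) {
    if (!found[r]) {
      mseq[r] = NA_STRING;
      mqual[r] = NA_STRING;
      mlen[r] = NA_INTEGER;
      continue;
    }
    std::string s1 = as<std::string>(seq1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2rc = revcomp_one(as<std::string>(seq2[r]));
    std::string q2rc = as<std::string>(qual2[r]);
    std::reverse(q2rc.begin(), q2rc.end());
    const int len1 = (int)s1.size(), len2 = (int)s2rc.size();
    const int o = offset[r];
    std::string ms, mq;
    if (o >= 0) {
      // fragment spans R1 start to revcomp(R2) end: length o + len2 (or len1
      // if R2 ends inside R1)
      const int total = std::max(len1, o + len2);
      ms.assign(total, 'N');
      mq.assign(total, '!');
      for (int i = 0; i < len1; ++i) { ms[i] = s1[i]; mq[i] = q1[i]; }
      for (int i = 0; i < len2; ++i) {
        int p = o + i;
        if (p >= len1) { ms[p] = s2rc[i]; mq[p] = q2rc[i]; continue; }
        // overlapped position: higher quality wins, tie goes to R1
        if (s1[p] == s2rc[i]) {
          mq[p] = std::max(q1[p], q2rc[i]);
        } else if ((unsigned char)q2rc[i] > (unsigned char)q1[p]) {
          ms[p] = s2rc[i];
          mq[p] = q2rc[i];
        }
      }
    } else {
      // read-through: fragment is the overlap window itself
      const int ov = std::min(len1, len2 + o);
      ms.assign(ov, 'N');
      mq.assign(ov, '!');
      for (int i = 0; i < ov; ++i) {
        int i2 = i - o;
        char b1 = s1[i], b2 = s2rc[i2];
        char c1 = q1[i], c2 = q2rc[i2];
        if (b1 == b2) {
          ms[i] = b1;
          mq[i] = std::max(c1, c2);
        } else if ((unsigned char)c2 > (unsigned char)c1) {
          ms[i] = b2;
          mq[i] = c2;
        } else {
          ms[i] = b1;
          mq[i] = c1;
        }
      }
    }
    mseq[r] = ms;
    mqual[r] = mq;
    mlen[r] = (int)ms.size();
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["length"] = mlen);
}
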