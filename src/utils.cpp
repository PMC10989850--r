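#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default: return 0;
  }
}

std::string revcomp_one(const std::string &s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(s[n - 1 - i]);
    if (c == 0)
      stop("invalid base '%s' in sequence (allowed: A,C,G,T,N)",
           std::string(1, s[n - 1 - i]).c_str());
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = revcomp_one(as<std::string>(seqs[i]));
  }
  return out;
}

// index (1-based) of first read violating sequence-alphabet or quality-range
// invariants, 0 if all valid
// [[Rcpp::export]]
int cpp_first_invalid_read(CharacterVector seqs, CharacterVector quals) {
  const R_xlen_t n = seqs.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    size_t ls = strlen(s), lq = strlen(q);
    if (ls != lq) return (int)(i + 1);
    for (size_t j = 0; j < ls; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N')
        return (int)(i + 1);
      unsigned char qc = (unsigned char)q[j];
      if (qc < 33 || qc > 126) return (int)(i + 1);
    }
  }
  return 0;
}

// Phred score matrix (reads x cycles) rendered to Phred+33 strings row-wise;
// NA cells terminate the row (ragged lengths)
// [[Rcpp::export]]
CharacterVector cpp_phred_strings(IntegerMatrix scores) {
  const int n = scores.nrow(), m = scores.ncol();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < m; ++j) {
      int v = scores(i, j);
      if (v == NA_INTEGER) break;
      if (v < 0) v = 0;
      if (v > 93) v = 93;
      buf.push_back((char)(v + 33));
    }
    out[i] = buf;
  }
  return out;
}

// substitute bases: reads[idx[k]] position pos[k] (1-based) becomes repl[k]
// [[Rcpp::export]]
CharacterVector cpp_substitute_bases(CharacterVector seqs, IntegerVector idx,
                                     IntegerVector pos, CharacterVector repl) {
  CharacterVector out = clone(seqs);
  std::string cur;
  R_xlen_t last = -1;
  for (R_xlen_t k = 0; k < idx.size(); ++k) {
    R_xlen_t i = idx[k] - 1;
    if (i != last) {
      if (last >= 0) out[last] = cur;
      cur = as<std::string>(out[i]);
      last = i;
    }
    int p = pos[k] - 1;
    if (p < 0 || (size_t)p >= cur.size()) stop("substitution position out of range");
    cur[p] = CHAR(STRING_ELT(repl, k))[0];
  }
  if (last >= 0) out[last] = cur;
  return out;
}
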