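#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4; // N
  }
}

// One-pass per-cycle counters over a read batch. Matrices are 5 rows
// (A,C,G,T,N) x max_cycles columns; k-mers containing N are skipped.
// [[Rcpp::export]]
List cpp_qc_accumulate(CharacterVector seqs, CharacterVector quals, int kmer_k) {
  const R_xlen_t n = seqs.size();
  int max_cycles = 0;
  for (R_xlen_t r = 0; r < n; ++r) {
    int len = (int)strlen(CHAR(STRING_ELT(seqs, r)));
    if (len > max_cycles) max_cycles = len;
  }
  NumericMatrix base_counts(5, max_cycles), base_qual_sum(5, max_cycles);
  NumericVector qual_sum(max_cycles), cycle_count(max_cycles);
  const int n_kmers = (int)std::pow(4.0, kmer_k);
  NumericVector kmers(n_kmers);
  double total_bases = 0, q20 = 0, q30 = 0, gc = 0;

  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    const int len = (int)strlen(s);
    int code = 0, valid = 0; // rolling k-mer code
    const int mask = n_kmers / 4;
    for (int i = 0; i < len; ++i) {
      int b = base_index(s[i]);
      int ph = (unsigned char)q[i] - 33;
      base_counts(b, i) += 1;
      base_qual_sum(b, i) += ph;
      qual_sum[i] += ph;
      cycle_count[i] += 1;
      total_bases += 1;
      if (ph >= 20) ++q20;
      if (ph >= 30) ++q30;
      if (b == 1 || b == 2) ++gc;
      if (b == 4) {
        valid = 0; code = 0;
      } else {
        code = (code % mask) * 4 + b;
        if (++valid >= kmer_k) kmers[code] += 1;
      }
    }
  }
  return List::create(
      _["max_cycles"] = max_cycles, _["base_counts"] = base_counts,
      _["base_qual_sum"] = base_qual_sum, _["qual_sum"] = qual_sum,
      _["cycle_count"] = cycle_count, _["kmer_counts"] = kmers,
      _["total_reads"] = (double)n, _["total_bases"] = total_bases,
      _["q20_bases"] = q20, _["q30_bases"] = q30, _["gc_bases"] = gc);
}

// Substring counting for overrepresentation analysis: counts every substring
// of each requested length from every `sampling`-th read.
// [[Rcpp::export]]
List cpp_overrep_count(CharacterVector seqs, IntegerVector lengths,
                       int sampling) {
  std::unordered_map<std::string, long> counts;
  const R_xlen_t n = seqs.size();
  std::vector<double> positions_sampled(lengths.size(), 0);
  for (R_xlen_t r = 0; r < n; r += sampling) {
    std::string s = as<std::string>(seqs[r]);
    const int len = (int)s.size();
    for (int li = 0; li < lengths.size(); ++li) {
      const int L = lengths[li];
      if (L > len) continue;
      positions_sampled[li] += len - L + 1;
      for (int p = 0; p + L <= len; ++p) counts[s.substr(p, L)] += 1;
    }
  }
  CharacterVector seq_out(counts.size());
  NumericVector count_out(counts.size());
  R_xlen_t i = 0;
  for (auto &kv : counts) {
    seq_out[i] = kv.first;
    count_out[i] = (double)kv.second;
    ++i;
  }
  return List::create(_["sequence"] = seq_out, _["count"] = count_out,
                      _["positions_sampled"] = NumericVector(
                          positions_sampled.begin(), positions_sampled.end()));
}

// per-starting-cycle hit counts of given query sequences over sampled reads;
// rows = queries, columns = starting cycle (1..max_cycles)
// [[Rcpp::export]]
NumericMatrix cpp_overrep_cycle_hits(CharacterVector seqs,
                                     CharacterVector queries, int sampling,
                                     int max_cycles) {
  NumericMatrix hits(queries.size(), max_cycles);
  std::vector<std::string> qs(queries.size());
  for (R_xlen_t k = 0; k < queries.size(); ++k)
    qs[k] = as<std::string>(queries[k]);
  for (R_xlen_t r = 0; r < seqs.size(); r += sampling) {
    std::string s = as<std::string>(seqs[r]);
    for (size_t k = 0; k < qs.size(); ++k) {
      const std::string &pat = qs[k];
      if (pat.size() > s.size()) continue;
      for (size_t p = 0; p + pat.size() <= s.size(); ++p) {
        if (s.compare(p, pat.size(), pat) == 0 && (int)p < max_cycles)
          hits(k, p) += 1;
      }
    }
  }
  return hits;
}
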