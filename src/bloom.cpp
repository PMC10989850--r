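#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// B bit arrays of L bits each with B independent seeded hash functions.
// A key is flagged duplicate iff its bit in every array is already set
// (no false negatives; false positives bounded by the standard bloom
// collision probability).
struct BloomIndex {
  int B;
  uint64_t L;
  std::vector<uint64_t> seeds;
  std::vector<std::vector<uint8_t>> arrays; // bit-packed, L/8 bytes each
  double reads_seen = 0;
  double duplicates_flagged = 0;
  double unique_inserted = 0;
  double expected_fp = 0; // running sum of per-insertion FP probability

  BloomIndex(int B_, uint64_t L_, const std::vector<uint64_t> &seeds_)
      : B(B_), L(L_), seeds(seeds_) {
    arrays.assign(B, std::vector<uint8_t>((size_t)((L + 7) / 8), 0));
  }
};

// FNV-1a 64-bit, seed-perturbed
static inline uint64_t fnv1a64(const char *s, size_t n, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ (seed * 0x9E3779B97F4A7C15ULL);
  for (size_t i = 0; i < n; ++i) {
    h ^= (unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  // final avalanche (splitmix64 tail) for better low-bit diffusion
  h ^= h >> 30; h *= 0xBF58476D1CE4E5B9ULL;
  h ^= h >> 27; h *= 0x94D049BB133111EBULL;
  h ^= h >> 31;
  return h;
}

// [[Rcpp::export]]
SEXP cpp_bloom_new(int B, double L, NumericVector seeds) {
  if (B < 1) stop("B must be >= 1");
  if (L < 1) stop("L must be >= 1");
  if ((int)seeds.size() != B) stop("need exactly B hash seeds");
  std::vector<uint64_t> sv(B);
  for (int b = 0; b < B; ++b) sv[b] = (uint64_t)seeds[b];
  XPtr<BloomIndex> ptr(new BloomIndex(B, (uint64_t)L, sv), true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cpp_hash_sequence(CharacterVector keys, double seed, double L) {
  const R_xlen_t n = keys.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(keys, i));
    out[i] = (double)(fnv1a64(s, strlen(s), (uint64_t)seed) % (uint64_t)L);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_check_insert(SEXP ptr_, CharacterVector keys) {
  XPtr<BloomIndex> ptr(ptr_);
  BloomIndex &bi = *ptr;
  const R_xlen_t n = keys.size();
  LogicalVector dup(n);
  const double Ld = (double)bi.L;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(keys, i));
    const size_t slen = strlen(s);
    bool all_set = true;
    std::vector<uint64_t> ps(bi.B);
    for (int b = 0; b < bi.B; ++b) {
      uint64_t p = fnv1a64(s, slen, bi.seeds[b]) % bi.L;
      ps[b] = p;
      if (!(bi.arrays[b][p >> 3] & (1u << (p & 7)))) all_set = false;
    }
    bi.reads_seen += 1;
    // FP probability of this check given the current fill level
    bi.expected_fp +=
        std::pow(1.0 - std::pow(1.0 - 1.0 / Ld, bi.unique_inserted), bi.B);
    if (all_set) {
      dup[i] = true;
      bi.duplicates_flagged += 1;
    } else {
      dup[i] = false;
      for (int b = 0; b < bi.B; ++b)
        bi.arrays[b][ps[b] >> 3] |= (uint8_t)(1u << (ps[b] & 7));
      bi.unique_inserted += 1;
    }
  }
  return dup;
}

// [[Rcpp::export]]
List cpp_bloom_state(SEXP ptr_) {
  XPtr<BloomIndex> ptr(ptr_);
  double bytes = 0;
  for (auto &a : ptr->arrays) bytes += (double)a.capacity();
  return List::create(
      _["B"] = ptr->B, _["L"] = (double)ptr->L,
      _["reads_seen"] = ptr->reads_seen,
      _["duplicates_flagged"] = ptr->duplicates_flagged,
      _["unique_inserted"] = ptr->unique_inserted,
      _["expected_false_positives"] = ptr->expected_fp,
      _["bytes"] = bytes);
}
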