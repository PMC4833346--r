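#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Canonical k-mer multiplicity histogram over a set of reads.
// k-mers containing any non-ACGT character are skipped; counting collapses a
// k-mer with its reverse complement (2-bit encoding, k <= 31 so a k-mer fits
// in one 64-bit word).
//
// Returns a two-column integer matrix (multiplicity, n_distinct_kmers),
// sorted by multiplicity.
// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
IntegerMatrix kmer_histogram_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  {
    // reserve for the worst case (every k-mer distinct) to avoid rehashing
    size_t total = 0;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
      SEXP el = STRING_ELT(reads, i);
      if (el != NA_STRING) total += LENGTH(el);
    }
    counts.reserve(total);
  }
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  int code[256];
  std::fill(code, code + 256, -1);
  code[(unsigned char)'A'] = 0; code[(unsigned char)'a'] = 0;
  code[(unsigned char)'C'] = 1; code[(unsigned char)'c'] = 1;
  code[(unsigned char)'G'] = 2; code[(unsigned char)'g'] = 2;
  code[(unsigned char)'T'] = 3; code[(unsigned char)'t'] = 3;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP el = STRING_ELT(reads, i);
    if (el == NA_STRING) continue;
    const char* s = CHAR(el);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char* p = s; *p; ++p) {
      int c = code[(unsigned char)*p];
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (valid < k) ++valid;
      if (valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint32_t, uint64_t> hist;
  for (const auto& kv : counts) ++hist[kv.second];
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (const auto& kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());

  IntegerMatrix out(mult.size(), 2);
  for (size_t j = 0; j < mult.size(); ++j) {
    out(j, 0) = (int)mult[j];
    uint64_t n = hist[mult[j]];
    out(j, 1) = (n > (uint64_t)INT32_MAX) ? NA_INTEGER : (int)n;
  }
  colnames(out) = CharacterVector::create("multiplicity", "count");
  return out;
}
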