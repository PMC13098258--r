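#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// splitmix64 finalizer applied to the 2-bit encoding of the canonical k-mer.
// The 64-bit value is truncated to its top 53 bits before return so it
// round-trips exactly through an R double.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// Distinct canonical k-mer hashes pooled across contigs, sorted ascending.
// canonical = min of the k-mer and its reverse complement under the 2-bit
// encoding A<C<G<T, which coincides with lexicographic order. k-mers
// containing non-ACGT characters are skipped. limit > 0 keeps only the
// `limit` smallest values (bottom-s sketch); limit = 0 keeps all.
// [[Rcpp::export]]
NumericVector kmer_hashes(CharacterVector contigs, int k, int limit) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> hv;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    SEXP el = STRING_ELT(contigs, ci);
    const char *s = CHAR(el);
    const int n = LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hv.push_back(mix64(canon) >> 11);
      }
    }
  }
  std::sort(hv.begin(), hv.end());
  hv.erase(std::unique(hv.begin(), hv.end()), hv.end());
  size_t keep = hv.size();
  if (limit > 0 && (size_t)limit < keep) keep = (size_t)limit;
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)hv[i];
  return out;
}

// Mismatch count between two equal-length sequences (Hamming numerator).
// [[Rcpp::export]]
int hamming_mismatches(CharacterVector a, CharacterVector b) {
  if (a.size() != 1 || b.size() != 1) stop("expected single sequences");
  SEXP ea = STRING_ELT(a, 0), eb = STRING_ELT(b, 0);
  if (LENGTH(ea) != LENGTH(eb))
    stop("sequences must have equal length for Hamming ANI");
  const char *pa = CHAR(ea), *pb = CHAR(eb);
  const int n = LENGTH(ea);
  int m = 0;
  for (int i = 0; i < n; ++i) if (pa[i] != pb[i]) ++m;
  return m;
}
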