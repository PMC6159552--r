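#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (incl. N) = 4 (invalid).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// splitmix64 finalizer; a fixed seed keeps sketches reproducible across
// runs and platforms.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Bottom-s MinHash sketch over canonical k-mers.
//
// The canonical form of a k-mer is the lexicographic minimum of the k-mer
// and its reverse complement, which for the A<C<G<T 2-bit encoding equals
// the numeric minimum of the two packed codes. k-mers containing any
// non-ACGT base are skipped. Hashes are truncated to their top 53 bits so
// that they are exactly representable as R doubles.
//
// [[Rcpp::export(name = ".sketch_cpp")]]
NumericVector sketch_cpp(std::string seq, int k, int s, double seed) {
  const int n = (int) seq.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (n < k) stop("sequence too short");
  const uint64_t hseed = (uint64_t) seed;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  uint64_t fwd = 0, rev = 0;
  int valid = 0; // length of current run of valid bases
  std::vector<uint64_t> hashes;
  hashes.reserve(n > k ? n - k + 1 : 1);

  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c == 4) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | (((uint64_t) (3 - c)) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      hashes.push_back(splitmix64(canon ^ hseed) >> 11); // top 53 bits
    }
  }
  if (hashes.empty()) stop("sequence too short"); // no valid k-mer window
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  int keep = std::min((int) hashes.size(), s);
  NumericVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = (double) hashes[i];
  return out;
}

// Count distinct canonical k-mers (exact-Jaccard oracle support for short
// sequences).
//
// [[Rcpp::export(name = ".count_canonical_kmers_cpp")]]
double count_canonical_kmers_cpp(std::string seq, int k) {
  const int n = (int) seq.size();
  if (n < k) stop("sequence too short");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  std::vector<uint64_t> kmers;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c == 4) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | (((uint64_t) (3 - c)) << (2 * (k - 1)));
    if (++valid >= k) kmers.push_back(fwd < rev ? fwd : rev);
  }
  std::sort(kmers.begin(), kmers.end());
  kmers.erase(std::unique(kmers.begin(), kmers.end()), kmers.end());
  return (double) kmers.size();
}
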