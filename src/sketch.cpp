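// Bottom-s MinHash sketching of canonical k-mers.
//
// K-mers (k <= 31) are 2-bit packed (A=0, C=1, G=2, T=3, first base in the
// most significant bits, so numeric order == lexicographic order), canonicalized
// as min(kmer, revcomp), and hashed with the splitmix64 finalizer plus a fixed
// salt. Hashes are truncated to their top 53 bits so every value is exactly
// representable as an R double.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const uint64_t MAGCAT_HASH_SALT = 0x5851f42d4c957f2dULL;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".sketch_hashes_cpp")]]
List sketch_hashes_cpp(CharacterVector seqs, int k, int s) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (s < 1) stop("sketch size s must be >= 1");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::unordered_set<uint64_t> hashes;

  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *seq = CHAR(STRING_ELT(seqs, si));
    size_t n = strlen(seq);
    if (n < (size_t)k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // length of current run of valid bases
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      // reverse complement accumulates at the high end
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        uint64_t h = splitmix64(canon ^ MAGCAT_HASH_SALT) >> 11;  // top 53 bits
        hashes.insert(h);
      }
    }
  }

  double n_distinct = (double)hashes.size();
  std::vector<uint64_t> v(hashes.begin(), hashes.end());
  size_t keep = std::min((size_t)s, v.size());
  std::partial_sort(v.begin(), v.begin() + keep, v.end());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)v[i];
  return List::create(_["hashes"] = out, _["n_distinct"] = n_distinct);
}

// Mash Jaccard estimator on two sorted bottom-s hash lists: merge, take the
// s' = min(s, |union|) smallest values X, return |X in both| / |X|.
// [[Rcpp::export(name = ".jaccard_sorted_cpp")]]
double jaccard_sorted_cpp(NumericVector a, NumericVector b, int s) {
  R_xlen_t i = 0, j = 0, taken = 0, shared = 0;
  while (taken < s && (i < a.size() || j < b.size())) {
    if (i < a.size() && j < b.size()) {
      if (a[i] == b[j]) { ++shared; ++i; ++j; }
      else if (a[i] < b[j]) { ++i; }
      else { ++j; }
    } else if (i < a.size()) {
      ++i;
    } else {
      ++j;
    }
    ++taken;
  }
  if (taken == 0) return NA_REAL;
  return (double)shared / (double)taken;
}

// Exact Hamming mismatch fraction between equal-length sequences (truth helper).
// [[Rcpp::export(name = ".mismatch_fraction_cpp")]]
double mismatch_fraction_cpp(CharacterVector x, CharacterVector y) {
  const char *a = CHAR(STRING_ELT(x, 0));
  const char *b = CHAR(STRING_ELT(y, 0));
  size_t na = strlen(a), nb = strlen(b);
  if (na != nb) stop("sequences must have equal length");
  if (na == 0) stop("empty sequences");
  size_t mm = 0;
  for (size_t i = 0; i < na; ++i) if (a[i] != b[i]) ++mm;
  return (double)mm / (double)na;
}
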