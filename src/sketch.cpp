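#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 2-bit base codes; A<C<G<T so numeric order of packed k-mers equals
// lexicographic order of the strings.
static inline int base_code(char b) {
  switch (b) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// MurmurHash3 64-bit finalizer: bijective uniform mixer.
static inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

// floor(2^64 / c) for c >= 2, computed without overflow:
// 2^64 = UINT64_MAX + 1.
static inline uint64_t keep_threshold(uint64_t c) {
  uint64_t t = UINT64_MAX / c;
  if (UINT64_MAX % c == c - 1) t += 1;
  return t;
}

struct Params {
  int k;
  uint64_t c;
  uint64_t seed;
  uint64_t thresh;
  uint64_t mask;
  int shift; // 2*(k-1)
};

static Params make_params(int k, double c, double seed) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer between 3 and 31");
  if (c < 1) stop("c must be >= 1");
  Params p;
  p.k = k;
  p.c = (uint64_t)c;
  p.seed = (uint64_t)(int64_t)seed;
  p.thresh = p.c <= 1 ? UINT64_MAX : keep_threshold(p.c);
  p.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  p.shift = 2 * (k - 1);
  return p;
}

// Rolling canonical-k-mer scan; invalid bases reset the window so only
// fully ACGT windows are emitted.
template <typename F>
static void scan_kept_kmers(const char* s, size_t n, const Params& p, F emit) {
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int code = base_code(s[i]);
    if (code < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)code) & p.mask;
    rc = (rc >> 2) | (((uint64_t)(3 - code)) << p.shift);
    if (++run >= p.k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      uint64_t h = fmix64(canon ^ p.seed);
      if (p.c <= 1 || h < p.thresh) emit(h);
    }
  }
}

static RawVector hashes_to_raw(const std::vector<uint64_t>& v) {
  RawVector out(8 * v.size());
  uint8_t* dst = (uint8_t*)RAW(out);
  for (size_t i = 0; i < v.size(); ++i) {
    uint64_t h = v[i];
    for (int b = 0; b < 8; ++b) dst[8 * i + b] = (uint8_t)(h >> (8 * b));
  }
  return out;
}

static std::vector<uint64_t> raw_to_hashes(const RawVector& r) {
  if (r.size() % 8 != 0) stop("raw hash vector length must be a multiple of 8");
  size_t n = r.size() / 8;
  std::vector<uint64_t> v(n);
  const uint8_t* src = (const uint8_t*)RAW(r);
  for (size_t i = 0; i < n; ++i) {
    uint64_t h = 0;
    for (int b = 0; b < 8; ++b) h |= ((uint64_t)src[8 * i + b]) << (8 * b);
    v[i] = h;
  }
  return v;
}

// [[Rcpp::export]]
List cpp_sketch_reads(CharacterVector seqs, int k, double c, double seed) {
  Params p = make_params(k, c, seed);
  std::unordered_map<uint64_t, uint32_t> tab;
  double n_bases = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    n_bases += (double)n;
    scan_kept_kmers(s, n, p, [&](uint64_t h) { ++tab[h]; });
  }
  std::vector<std::pair<uint64_t, uint32_t>> entries(tab.begin(), tab.end());
  std::sort(entries.begin(), entries.end());
  std::vector<uint64_t> hs(entries.size());
  IntegerVector counts(entries.size());
  for (size_t i = 0; i < entries.size(); ++i) {
    hs[i] = entries[i].first;
    counts[i] = (int)entries[i].second;
  }
  return List::create(_["hashes"] = hashes_to_raw(hs),
                      _["counts"] = counts,
                      _["n_bases"] = n_bases,
                      _["n_reads"] = (double)seqs.size());
}

// [[Rcpp::export]]
List cpp_sketch_contigs(CharacterVector seqs, int k, double c, double seed) {
  Params p = make_params(k, c, seed);
  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    std::vector<uint64_t> hs;
    scan_kept_kmers(s, n, p, [&](uint64_t h) { hs.push_back(h); });
    std::sort(hs.begin(), hs.end());
    hs.erase(std::unique(hs.begin(), hs.end()), hs.end());
    out[i] = hashes_to_raw(hs);
  }
  return out;
}

// Multiplicities of the query hashes found in the sample table; both hash
// vectors must be sorted ascending (two-pointer sweep).
// [[Rcpp::export]]
IntegerVector cpp_match_counts(RawVector query_hashes, RawVector table_hashes,
                               IntegerVector table_counts) {
  std::vector<uint64_t> q = raw_to_hashes(query_hashes);
  std::vector<uint64_t> t = raw_to_hashes(table_hashes);
  if ((R_xlen_t)t.size() != table_counts.size())
    stop("table hash/count length mismatch");
  std::vector<int> out;
  size_t i = 0, j = 0;
  while (i < q.size() && j < t.size()) {
    if (q[i] < t[j]) ++i;
    else if (t[j] < q[i]) ++j;
    else { out.push_back(table_counts[j]); ++i; ++j; }
  }
  return wrap(out);
}

// Hash of the canonical form of each k-mer string; valid[i] = FALSE (and a
// zero hash slot) when the string has the wrong length or non-ACGT bases.
// [[Rcpp::export]]
List cpp_hash_kmers(CharacterVector kmers, int k, double seed) {
  Params p = make_params(k, 1, seed);
  std::vector<uint64_t> hs(kmers.size(), 0);
  LogicalVector valid(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    size_t n = LENGTH(STRING_ELT(kmers, i));
    bool seen = false;
    if ((int)n == k) {
      scan_kept_kmers(s, n, p, [&](uint64_t h) { hs[i] = h; seen = true; });
    }
    valid[i] = seen;
  }
  return List::create(_["hashes"] = hashes_to_raw(hs), _["valid"] = valid);
}

// [[Rcpp::export]]
LogicalVector cpp_keep_hashes(RawVector hashes, double c) {
  if (c < 1) stop("c must be >= 1");
  uint64_t cc = (uint64_t)c;
  uint64_t thresh = cc <= 1 ? UINT64_MAX : keep_threshold(cc);
  std::vector<uint64_t> v = raw_to_hashes(hashes);
  LogicalVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = (cc <= 1) || (v[i] < thresh);
  return out;
}

// Big-endian hex rendering so lexicographic order of the strings equals
// numeric order of the hashes.
// [[Rcpp::export]]
CharacterVector cpp_hash_hex(RawVector hashes) {
  static const char* digits = "0123456789abcdef";
  std::vector<uint64_t> v = raw_to_hashes(hashes);
  CharacterVector out(v.size());
  char buf[17];
  buf[16] = '\0';
  for (size_t i = 0; i < v.size(); ++i) {
    uint64_t h = v[i];
    for (int d = 15; d >= 0; --d) { buf[d] = digits[h & 0xf]; h >>= 4; }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_hex_to_raw(CharacterVector hex) {
  std::vector<uint64_t> v(hex.size());
  for (R_xlen_t i = 0; i < hex.size(); ++i) {
    const char* s = CHAR(STRING_ELT(hex, i));
    if (LENGTH(STRING_ELT(hex, i)) != 16)
      stop("hex hash must be 16 characters");
    uint64_t h = 0;
    for (int d = 0; d < 16; ++d) {
      char ch = s[d];
      int nib;
      if (ch >= '0' && ch <= '9') nib = ch - '0';
      else if (ch >= 'a' && ch <= 'f') nib = ch - 'a' + 10;
      else if (ch >= 'A' && ch <= 'F') nib = ch - 'A' + 10;
      else stop("invalid hex character");
      h = (h << 4) | (uint64_t)nib;
    }
    v[i] = h;
  }
  return hashes_to_raw(v);
}
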