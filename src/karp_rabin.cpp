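#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Karp-Rabin multi-pattern exact search over a four-letter alphabet.
// Base-4 polynomial rolling hash modulo the Mersenne prime 2^61 - 1;
// one hash table per distinct pattern length; every hash hit is verified
// by direct byte comparison, so collisions cannot produce false matches.
// Windows containing a non-ACGT character (N and friends) never match.

static const uint64_t KR_MOD = (1ULL << 61) - 1;

static inline uint64_t mulmod(uint64_t a, uint64_t b) {
  unsigned __int128 p = (unsigned __int128)a * b;
  uint64_t lo = (uint64_t)(p & KR_MOD);
  uint64_t hi = (uint64_t)(p >> 61);
  uint64_t s = lo + hi;
  if (s >= KR_MOD) s -= KR_MOD;
  return s;
}

static inline uint64_t addmod(uint64_t a, uint64_t b) {
  uint64_t s = a + b;
  if (s >= KR_MOD) s -= KR_MOD;
  return s;
}

static inline int base4(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
DataFrame kr_search_cpp(CharacterVector sequences, CharacterVector patterns) {
  const int nseq = sequences.size();
  const int npat = patterns.size();

  std::vector<std::string> pats(npat);
  std::vector<int> plen(npat);
  // group pattern indices by length
  std::unordered_map<int, std::vector<int> > by_len;
  for (int i = 0; i < npat; ++i) {
    pats[i] = as<std::string>(patterns[i]);
    plen[i] = (int)pats[i].size();
    if (plen[i] == 0) stop("empty pattern");
    for (char c : pats[i])
      if (base4(c) < 0) stop("pattern contains a non-ACGT character");
    by_len[plen[i]].push_back(i);
  }

  std::vector<int> out_pat, out_chrom, out_start;

  for (auto& grp : by_len) {
    const int L = grp.first;
    // hash table: pattern hash -> pattern indices
    std::unordered_multimap<uint64_t, int> table;
    table.reserve(grp.second.size() * 2);
    for (int pi : grp.second) {
      uint64_t h = 0;
      for (int k = 0; k < L; ++k) h = addmod(mulmod(h, 4), (uint64_t)base4(pats[pi][k]));
      table.insert(std::make_pair(h, pi));
    }
    // 4^(L-1) mod KR_MOD, for removing the leading character
    uint64_t lead = 1;
    for (int k = 0; k < L - 1; ++k) lead = mulmod(lead, 4);

    for (int ci = 0; ci < nseq; ++ci) {
      const char* s = CHAR(STRING_ELT(sequences, ci));
      const int n = (int)std::strlen(s);
      if (n < L) continue;
      uint64_t h = 0;
      int valid = 0;  // number of consecutive valid (ACGT) chars ending at current pos
      for (int i = 0; i < n; ++i) {
        int c = base4(s[i]);
        if (c < 0) { valid = 0; h = 0; continue; }
        if (valid >= L) {
          // drop s[i - L]
          uint64_t drop = mulmod((uint64_t)base4(s[i - L]), lead);
          h = addmod(h, KR_MOD - drop);
          h = addmod(mulmod(h, 4), (uint64_t)c);
        } else {
          h = addmod(mulmod(h, 4), (uint64_t)c);
          ++valid;
        }
        if (valid >= L) {
          const int start = i - L + 1;
          auto range = table.equal_range(h);
          for (auto it = range.first; it != range.second; ++it) {
            const int pi = it->second;
            if (std::memcmp(s + start, pats[pi].data(), L) == 0) {
              out_pat.push_back(pi + 1);
              out_chrom.push_back(ci + 1);
              out_start.push_back(start);
            }
          }
        }
      }
    }
  }

  return DataFrame::create(Named("pattern") = out_pat,
                           Named("chrom") = out_chrom,
                           Named("start") = out_start);
}
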