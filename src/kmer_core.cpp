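// Canonical k-mer counting core. Words are 2-bit encoded (A=0, C=1, G=2,
// T=3), so numeric comparison of equal-length codes is lexicographic order
// and the canonical form min(word, revcomp) matches the string definition.
// k is restricted to odd values <= 31 upstream (62 bits, no palindromes).
// Counting collects all window codes and sorts them (fast and memory-cheap
// at the read volumes used here), so profiles come out lexicographically
// sorted and runs of equal codes give the multiplicities.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstdint>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static void collect_codes(SEXP seqs, int k, std::vector<uint64_t> &codes) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  R_xlen_t n = Rf_xlength(seqs);
  R_xlen_t total = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    total += Rf_xlength(STRING_ELT(seqs, s));
  codes.reserve((size_t)total);
  for (R_xlen_t s = 0; s < n; ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char *p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) codes.push_back(fwd < rev ? fwd : rev);
    }
  }
  std::sort(codes.begin(), codes.end());
}

// Multiplicity histogram: m -> number of distinct canonical k-mers seen m times.
// [[Rcpp::export]]
List cpp_kmer_histogram(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> codes;
  collect_codes(seqs, k, codes);
  std::map<int, double> h;
  size_t i = 0, n = codes.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    h[(int)(j - i)] += 1.0;
    i = j;
  }
  IntegerVector m(h.size());
  NumericVector f(h.size());
  R_xlen_t t = 0;
  for (std::map<int, double>::const_iterator it = h.begin(); it != h.end();
       ++it, ++t) {
    m[t] = it->first;
    f[t] = it->second;
  }
  return List::create(_["m"] = m, _["count"] = f);
}

static std::string decode(uint64_t code, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = B[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Full profile: canonical k-mer strings and counts, lexicographic order.
// [[Rcpp::export]]
List cpp_kmer_profile(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> codes;
  collect_codes(seqs, k, codes);
  std::vector<uint64_t> uniq;
  std::vector<int> cnt;
  size_t i = 0, n = codes.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    uniq.push_back(codes[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
  R_xlen_t m = uniq.size();
  CharacterVector words(m);
  IntegerVector counts(m);
  for (R_xlen_t t = 0; t < m; ++t) {
    words[t] = decode(uniq[t], k);
    counts[t] = cnt[t];
  }
  return List::create(_["kmer"] = words, _["count"] = counts);
}

// Zero-order background probability P(w) + P(revcomp(w)) for each word,
// given base probabilities p = (pA, pC, pG, pT). Palindromes get one term.
// [[Rcpp::export]]
NumericVector cpp_word_background(CharacterVector words, NumericVector p) {
  if (p.size() != 4) stop("p must have length 4 (A, C, G, T)");
  R_xlen_t n = words.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(words, i));
    double pf = 1.0, pr = 1.0;
    bool palindrome = true;
    int len = 0;
    for (const char *q = w; *q; ++q) ++len;
    for (int j = 0; j < len; ++j) {
      int c = base_code(w[j]);
      int cr = base_code(w[len - 1 - j]);
      if (c < 0 || cr < 0) { pf = NA_REAL; break; }
      pf *= p[c];
      pr *= p[3 - cr];
      if (w[j] != "ACGT"[3 - cr]) palindrome = false;
    }
    out[i] = palindrome ? pf : pf + pr;
  }
  return out;
}
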