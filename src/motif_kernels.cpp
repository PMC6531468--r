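#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, U/T=3; anything else (N, ...) = -1.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// Rolling k-mer codes for one sequence; code[i] = encoded k-mer starting at i
// (0-based), or -1 where the window contains an ambiguous base.
static void kmer_codes(const char *s, int len, int k, std::vector<int> &out) {
  out.assign(len >= k ? len - k + 1 : 0, -1);
  if (len < k) return;
  int mask = (1 << (2 * k)) - 1;
  int code = 0, valid = 0; // valid = number of consecutive valid bases ending here
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= k) out[i - k + 1] = code;
  }
}

// Tag-containment counts over the full 4^k universe: each sequence adds at
// most 1 to each k-mer it contains.
// [[Rcpp::export]]
IntegerVector kmer_containment_counts_cpp(CharacterVector seqs, int k) {
  const int n_kmers = 1 << (2 * k);
  IntegerVector counts(n_kmers);
  std::vector<int> last_seen(n_kmers, -1), codes;
  for (int t = 0; t < seqs.size(); ++t) {
    if (seqs[t] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(seqs, t));
    kmer_codes(s, (int)std::strlen(s), k, codes);
    for (size_t i = 0; i < codes.size(); ++i) {
      int c = codes[i];
      if (c >= 0 && last_seen[c] != t) { last_seen[c] = t; ++counts[c]; }
    }
  }
  return counts;
}

// Ordered tetramer-pair spacing counts: rows = 65,536 pair codes
// (m1 * 256 + m2), columns = gap 0..max_gap; gap is the number of
// nucleotides strictly between the end of m1 and the start of m2.
// A tag contributes at most 1 per (pair, gap) cell.
// [[Rcpp::export]]
IntegerMatrix pair_spacing_counts_cpp(CharacterVector seqs, int max_gap) {
  const int k = 4, n_pairs = 1 << 16, n_gaps = max_gap + 1;
  IntegerMatrix counts(n_pairs, n_gaps);
  std::vector<int> last_seen((size_t)n_pairs * n_gaps, -1), codes;
  for (int t = 0; t < seqs.size(); ++t) {
    if (seqs[t] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(seqs, t));
    kmer_codes(s, (int)std::strlen(s), k, codes);
    int n = (int)codes.size();
    for (int i = 0; i < n; ++i) {
      if (codes[i] < 0) continue;
      int jmax = std::min(n - 1, i + k + max_gap);
      for (int j = i + k; j <= jmax; ++j) {
        if (codes[j] < 0) continue;
        int gap = j - i - k;
        size_t cell = (size_t)(codes[i] * 256 + codes[j]) * n_gaps + gap;
        if (last_seen[cell] != t) {
          last_seen[cell] = t;
          ++counts(codes[i] * 256 + codes[j], gap);
        }
      }
    }
  }
  return counts;
}

// Per-sequence motif containment flag (exact substring, no ambiguity match).
// [[Rcpp::export]]
LogicalVector seq_contains_motif_cpp(CharacterVector seqs, std::string motif) {
  int k = (int)motif.size();
  std::vector<int> mcode_v;
  kmer_codes(motif.c_str(), k, k, mcode_v);
  if (mcode_v.empty() || mcode_v[0] < 0) stop("motif contains ambiguous bases");
  int mcode = mcode_v[0];
  LogicalVector out(seqs.size());
  std::vector<int> codes;
  for (int t = 0; t < seqs.size(); ++t) {
    if (seqs[t] == NA_STRING) { out[t] = false; continue; }
    const char *s = CHAR(STRING_ELT(seqs, t));
    kmer_codes(s, (int)std::strlen(s), k, codes);
    bool found = false;
    for (size_t i = 0; i < codes.size() && !found; ++i) found = codes[i] == mcode;
    out[t] = found;
  }
  return out;
}

// Per-sequence flag: contains m1 and m2 (tetramers) at exactly the given gap.
// [[Rcpp::export]]
LogicalVector seq_contains_pair_cpp(CharacterVector seqs, std::string m1,
                                    std::string m2, int gap) {
  const int k = 4;
  if ((int)m1.size() != k || (int)m2.size() != k) stop("pair motifs must be tetramers");
  std::vector<int> c1, c2;
  kmer_codes(m1.c_str(), k, k, c1);
  kmer_codes(m2.c_str(), k, k, c2);
  if (c1[0] < 0 || c2[0] < 0) stop("pair motifs contain ambiguous bases");
  LogicalVector out(seqs.size());
  std::vector<int> codes;
  for (int t = 0; t < seqs.size(); ++t) {
    if (seqs[t] == NA_STRING) { out[t] = false; continue; }
    const char *s = CHAR(STRING_ELT(seqs, t));
    kmer_codes(s, (int)std::strlen(s), k, codes);
    int n = (int)codes.size();
    bool found = false;
    for (int i = 0; i + k + gap < n && !found; ++i)
      found = codes[i] == c1[0] && codes[i + k + gap] == c2[0];
    out[t] = found;
  }
  return out;
}
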