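// Contextual feature kernels: mismatch-tolerant k-mer probability tensors,
// positional k-mer encoding, and sliding-window dinucleotide densities.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// increment tensor rows for all codes within Hamming distance <= m_left of
// the current code (recursion over substituted positions, left to right)
static void bump_ball(std::vector<int>& counts, int nrow, int col,
                      int code, int k, int from, int m_left) {
  counts[(size_t)col * nrow + code]++;
  if (m_left == 0) return;
  for (int p = from; p < k; ++p) {
    int shift = 2 * (k - 1 - p);
    int orig = (code >> shift) & 3;
    int base_cleared = code & ~(3 << shift);
    for (int b = 0; b < 4; ++b) {
      if (b == orig) continue;
      bump_ball(counts, nrow, col, base_cleared | (b << shift), k, p + 1, m_left - 1);
    }
  }
}

// cell[m, p] = fraction of sequences whose k-mer at position p lies within
// Hamming distance <= budget of k-mer m.  Windows containing N are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_tensor(CharacterVector seqs, int k, int budget) {
  const int ns = seqs.size();
  if (ns == 0) stop("no sequences");
  const int L = LENGTH(STRING_ELT(seqs, 0));
  const int P = L - k + 1;
  if (P < 1) stop("sequences shorter than k");
  const int nrow = 1 << (2 * k);
  std::vector<int> counts((size_t)nrow * P, 0);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != L) stop("sequences must have equal length");
    std::vector<int> sc(L);
    for (int j = 0; j < L; ++j) sc[j] = base_code(s[j]);
    int code = 0, bad = 0;
    for (int j = 0; j < L; ++j) {
      int b = sc[j];
      code = ((code << 2) | (b < 0 ? 0 : b)) & (nrow - 1);
      bad = b < 0 ? k : (bad > 0 ? bad - 1 : 0);
      int p = j - k + 1;
      if (p >= 0 && bad == 0)
        bump_ball(counts, nrow, p, code, k, 0, budget);
    }
  }
  NumericMatrix out(nrow, P);
  for (int p = 0; p < P; ++p)
    for (int m = 0; m < nrow; ++m)
      out(m, p) = (double)counts[(size_t)p * nrow + m] / ns;
  return out;
}

// per-sequence positional k-mer codes (0-based codes; NA where the window
// contains a non-ACGU symbol); ns x (L - k + 1)
// [[Rcpp::export]]
IntegerMatrix cpp_encode_kmers(CharacterVector seqs, int k) {
  const int ns = seqs.size();
  if (ns == 0) stop("no sequences");
  const int L = LENGTH(STRING_ELT(seqs, 0));
  const int P = L - k + 1;
  if (P < 1) stop("sequences shorter than k");
  const int mask = (1 << (2 * k)) - 1;
  IntegerMatrix out(ns, P);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != L) stop("sequences must have equal length");
    int code = 0, bad = 0;
    for (int j = 0; j < L; ++j) {
      int b = base_code(s[j]);
      code = ((code << 2) | (b < 0 ? 0 : b)) & mask;
      bad = b < 0 ? k : (bad > 0 ? bad - 1 : 0);
      int p = j - k + 1;
      if (p >= 0) out(i, p) = bad == 0 ? code : NA_INTEGER;
    }
  }
  return out;
}

// Sliding-window dinucleotide densities: for each placement of a window of
// `window` bases (step 1), the 16 dinucleotide counts / (window - 1).
// Output: ns x (16 * n_placements); per placement the 16 columns follow
// AA, AC, AG, AU, CA, ..., UU order.  Windows touching an N give NA.
// [[Rcpp::export]]
NumericMatrix cpp_dinuc_densities(CharacterVector seqs, int window) {
  const int ns = seqs.size();
  if (ns == 0) stop("no sequences");
  const int L = LENGTH(STRING_ELT(seqs, 0));
  if (window < 2 || window > L) stop("window must be in [2, sequence length]");
  const int npl = L - window + 1;
  NumericMatrix out(ns, 16 * npl);
  const double denom = window - 1;
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != L) stop("sequences must have equal length");
    std::vector<int> di(L - 1);
    for (int j = 0; j < L - 1; ++j) {
      int a = base_code(s[j]), b = base_code(s[j + 1]);
      di[j] = (a < 0 || b < 0) ? -1 : 4 * a + b;
    }
    std::vector<int> cnt(16, 0);
    int nbad = 0;
    for (int j = 0; j < window - 1; ++j) {
      if (di[j] < 0) ++nbad; else cnt[di[j]]++;
    }
    for (int p = 0;; ++p) {
      for (int d = 0; d < 16; ++d)
        out(i, 16 * p + d) = nbad > 0 ? NA_REAL : cnt[d] / denom;
      if (p == npl - 1) break;
      int old = di[p], add = di[p + window - 1];
      if (old < 0) --nbad; else cnt[old]--;
      if (add < 0) ++nbad; else cnt[add]++;
    }
  }
  return out;
}
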