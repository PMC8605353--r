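// Burrows-Wheeler transform / FM-index over concatenated RNA sequences.
//
// Alphabet encoding inside the index: 0 = terminal sentinel, 1 = per-sequence
// separator, 2..5 = A,C,G,U.  Queries are encoded over 2..5 only, so a
// backward-search match can never straddle a separator.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
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

static const char BASES[4] = {'A', 'C', 'G', 'U'};

// Suffix array by prefix doubling.  With a unique smallest sentinel at the
// end, sorting suffixes is equivalent to sorting rotations.
static std::vector<int> build_sa(const std::vector<int>& s) {
  const int n = (int)s.size();
  std::vector<int> sa(n), rk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rk[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      int ra = a + k < n ? rk[a + k] : -1;
      int rb = b + k < n ? rk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rk = tmp;
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// [[Rcpp::export]]
std::string cpp_bwt(std::string text) {
  // text arrives with its sentinel already appended; treat bytes literally
  const int n = (int)text.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = (unsigned char)text[i];
  std::vector<int> sa = build_sa(s);
  std::string out(n, ' ');
  for (int i = 0; i < n; ++i) out[i] = text[(sa[i] + n - 1) % n];
  return out;
}

struct FMCore {
  std::vector<int> bwt;         // transformed text, symbol codes 0..5
  std::vector<int> C;           // first-column cumulative counts, length 7
  std::vector<int> occ;         // checkpointed ranks, every SAMPLE rows x 6 symbols
  std::vector<int> sa;          // full suffix array (locate support)
  std::vector<int> seq_start;   // start offset of each sequence in the text
  std::vector<int> seq_len;
  int n;                        // text length incl. sentinel
  static const int SAMPLE = 32;

  int rank(int sym, int i) const {      // # of sym in bwt[0, i)
    int cp = i / SAMPLE;
    int r = occ[(size_t)cp * 6 + sym];
    for (int j = cp * SAMPLE; j < i; ++j) if (bwt[j] == sym) ++r;
    return r;
  }
  // backward search; returns [lo, hi) suffix-array range, empty if lo >= hi
  void search(const std::vector<int>& q, int& lo, int& hi) const {
    lo = 0; hi = n;
    for (int j = (int)q.size() - 1; j >= 0 && lo < hi; --j) {
      int c = q[j];
      lo = C[c] + rank(c, lo);
      hi = C[c] + rank(c, hi);
    }
  }
};

static FMCore core_from_list(const List& idx) {
  FMCore fm;
  fm.bwt = as<std::vector<int>>(idx["bwt"]);
  fm.C = as<std::vector<int>>(idx["first_column_ranks"]);
  fm.occ = as<std::vector<int>>(idx["occurrence_table"]);
  fm.sa = as<std::vector<int>>(idx["sampled_positions"]);
  fm.seq_start = as<std::vector<int>>(idx["seq_start"]);
  fm.seq_len = as<std::vector<int>>(idx["seq_len"]);
  fm.n = as<int>(idx["text_length"]);
  return fm;
}

// [[Rcpp::export]]
List cpp_fm_build(CharacterVector seqs) {
  const int ns = seqs.size();
  std::vector<int> text;
  std::vector<int> seq_start(ns), seq_len(ns);
  size_t total = 0;
  for (int i = 0; i < ns; ++i) total += LENGTH(STRING_ELT(seqs, i)) + 1;
  text.reserve(total);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    seq_start[i] = (int)text.size();
    seq_len[i] = (int)s.size();
    for (char c : s) {
      int b = base_code(c);
      if (b < 0) stop("sequence %d contains a non-ACGU symbol ('%c')", i + 1, c);
      text.push_back(b + 2);
    }
    if (i < ns - 1) text.push_back(1);   // separator
  }
  text.push_back(0);                      // sentinel
  const int n = (int)text.size();

  std::vector<int> sa = build_sa(text);
  std::vector<int> bwt(n);
  for (int i = 0; i < n; ++i) bwt[i] = text[(sa[i] + n - 1) % n];

  std::vector<int> cnt(6, 0);
  for (int i = 0; i < n; ++i) cnt[text[i]]++;
  std::vector<int> C(7, 0);
  for (int s = 0; s < 6; ++s) C[s + 1] = C[s] + cnt[s];

  int ncp = n / FMCore::SAMPLE + 1;
  std::vector<int> occ((size_t)ncp * 6, 0);
  std::vector<int> run(6, 0);
  // i runs to n inclusive so the final checkpoint row is written even when
  // n is an exact multiple of the sampling interval
  for (int i = 0; i <= n; ++i) {
    if (i % FMCore::SAMPLE == 0)
      for (int s = 0; s < 6; ++s) occ[(size_t)(i / FMCore::SAMPLE) * 6 + s] = run[s];
    if (i < n) run[bwt[i]]++;
  }

  return List::create(
    _["bwt"] = bwt, _["first_column_ranks"] = C, _["occurrence_table"] = occ,
    _["sampled_positions"] = sa, _["seq_start"] = seq_start,
    _["seq_len"] = seq_len, _["text_length"] = n, _["n_seq"] = ns);
}

static bool encode_query(const std::string& q, std::vector<int>& out) {
  out.resize(q.size());
  for (size_t i = 0; i < q.size(); ++i) {
    int b = base_code(q[i]);
    if (b < 0) return false;
    out[i] = b + 2;
  }
  return true;
}

// map a global text position to (sequence index, offset)
static inline int pos_to_seq(const FMCore& fm, int pos, int& off) {
  int lo = 0, hi = (int)fm.seq_start.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (fm.seq_start[mid] <= pos) lo = mid; else hi = mid - 1;
  }
  off = pos - fm.seq_start[lo];
  return lo;
}

// [[Rcpp::export]]
IntegerMatrix cpp_fm_locate(List idx, std::string query) {
  FMCore fm = core_from_list(idx);
  std::vector<int> q;
  if (query.empty() || !encode_query(query, q))
    return IntegerMatrix(0, 2);
  int lo, hi;
  fm.search(q, lo, hi);
  if (lo >= hi) return IntegerMatrix(0, 2);
  std::vector<std::pair<int,int>> hits;
  for (int r = lo; r < hi; ++r) {
    int off, sid = pos_to_seq(fm, fm.sa[r], off);
    hits.push_back(std::make_pair(sid, off));
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first;   // 0-based sequence index
    out(i, 1) = hits[i].second;  // 0-based offset
  }
  return out;
}

// enumerate all k-mers within Hamming distance <= m of root (codes 0..3)
static void ball_rec(std::vector<int>& cur, const std::vector<int>& root,
                     int from, int m_left,
                     std::vector<std::vector<int>>& out) {
  out.push_back(cur);
  if (m_left == 0) return;
  const int k = (int)root.size();
  for (int p = from; p < k; ++p) {
    int orig = cur[p];
    for (int b = 0; b < 4; ++b) {
      if (b == orig) continue;
      cur[p] = b;
      ball_rec(cur, root, p + 1, m_left - 1, out);
    }
    cur[p] = orig;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate_relatives(std::string root, int max_mismatches) {
  const int k = (int)root.size();
  std::vector<int> rc(k);
  for (int i = 0; i < k; ++i) {
    int b = base_code(root[i]);
    if (b < 0) stop("root contains a non-ACGU symbol");
    rc[i] = b;
  }
  std::vector<std::vector<int>> mem;
  std::vector<int> cur = rc;
  ball_rec(cur, rc, 0, max_mismatches, mem);
  CharacterVector out(mem.size());
  std::string buf(k, ' ');
  for (size_t i = 0; i < mem.size(); ++i) {
    for (int j = 0; j < k; ++j) buf[j] = BASES[mem[i][j]];
    out[i] = buf;
  }
  return out;
}

// union of FM hits over the Hamming ball of root
// [[Rcpp::export]]
IntegerMatrix cpp_fm_inexact_locate(List idx, std::string root, int max_mismatches) {
  FMCore fm = core_from_list(idx);
  const int k = (int)root.size();
  std::vector<int> rc(k);
  for (int i = 0; i < k; ++i) {
    int b = base_code(root[i]);
    if (b < 0) return IntegerMatrix(0, 3);
    rc[i] = b;
  }
  std::vector<std::vector<int>> mem;
  std::vector<int> cur = rc;
  ball_rec(cur, rc, 0, max_mismatches, mem);
  std::vector<std::array<int,3>> hits;    // seq, offset, mismatches
  std::vector<int> q(k);
  for (const auto& rel : mem) {
    int mm = 0;
    for (int j = 0; j < k; ++j) { if (rel[j] != rc[j]) ++mm; q[j] = rel[j] + 2; }
    int lo, hi;
    fm.search(q, lo, hi);
    for (int r = lo; r < hi; ++r) {
      int off, sid = pos_to_seq(fm, fm.sa[r], off);
      hits.push_back({sid, off, mm});
    }
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out((int)hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i][0]; out(i, 1) = hits[i][1]; out(i, 2) = hits[i][2];
  }
  return out;
}

// For every one of the 4^k possible k-mer roots, count the number of indexed
// sequences containing the root or any relative within the mismatch budget.
// [[Rcpp::export]]
IntegerVector cpp_fm_seed_scan(List idx, int k, int max_mismatches) {
  FMCore fm = core_from_list(idx);
  const int nroot = 1 << (2 * k);
  const int nseq = (int)fm.seq_start.size();
  IntegerVector out(nroot);
  std::vector<int> stamp(nseq, -1);
  std::vector<int> rc(k), q(k);
  for (int root = 0; root < nroot; ++root) {
    for (int j = 0; j < k; ++j) rc[j] = (root >> (2 * (k - 1 - j))) & 3;
    std::vector<std::vector<int>> mem;
    std::vector<int> cur = rc;
    ball_rec(cur, rc, 0, max_mismatches, mem);
    int count = 0;
    for (const auto& rel : mem) {
      for (int j = 0; j < k; ++j) q[j] = rel[j] + 2;
      int lo, hi;
      fm.search(q, lo, hi);
      for (int r = lo; r < hi; ++r) {
        int off, sid = pos_to_seq(fm, fm.sa[r], off);
        if (stamp[sid] != root) { stamp[sid] = root; ++count; }
      }
    }
    out[root] = count;
  }
  return out;
}

// Total occurrence count (not per-sequence presence) of every possible
// k-mer root within the mismatch budget: sum of suffix-array range sizes
// over the Hamming ball.
// [[Rcpp::export]]
IntegerVector cpp_fm_seed_occurrence(List idx, int k, int max_mismatches) {
  FMCore fm = core_from_list(idx);
  const int nroot = 1 << (2 * k);
  IntegerVector out(nroot);
  std::vector<int> rc(k), q(k);
  for (int root = 0; root < nroot; ++root) {
    for (int j = 0; j < k; ++j) rc[j] = (root >> (2 * (k - 1 - j))) & 3;
    std::vector<std::vector<int>> mem;
    std::vector<int> cur = rc;
    ball_rec(cur, rc, 0, max_mismatches, mem);
    long total = 0;
    for (const auto& rel : mem) {
      for (int j = 0; j < k; ++j) q[j] = rel[j] + 2;
      int lo, hi;
      fm.search(q, lo, hi);
      total += hi - lo;
    }
    out[root] = (int)total;
  }
  return out;
}

// Direct mismatch-tolerant scan of a pattern across sequences.
// Returns, per sequence, all 0-based start positions with Hamming distance
// <= budget (windows containing N never match).
// [[Rcpp::export]]
List cpp_hamming_scan(CharacterVector seqs, std::string pattern, int budget) {
  const int k = (int)pattern.size();
  std::vector<int> pc(k);
  for (int i = 0; i < k; ++i) {
    pc[i] = base_code(pattern[i]);
    if (pc[i] < 0) stop("pattern contains a non-ACGU symbol");
  }
  const int ns = seqs.size();
  List out(ns);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    std::vector<int> sc(L);
    for (int j = 0; j < L; ++j) sc[j] = base_code(s[j]);
    std::vector<int> hits;
    for (int p = 0; p + k <= L; ++p) {
      int mm = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (sc[p + j] < 0) { ok = false; break; }
        if (sc[p + j] != pc[j] && ++mm > budget) { ok = false; break; }
      }
      if (ok) hits.push_back(p);
    }
    out[i] = wrap(hits);
  }
  return out;
}

// Best (fewest-mismatch, then leftmost) match of pattern per sequence.
// Returns an ns x 2 matrix: position (0-based, -1 if none) and mismatches.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_best(CharacterVector seqs, std::string pattern, int budget) {
  const int k = (int)pattern.size();
  std::vector<int> pc(k);
  for (int i = 0; i < k; ++i) {
    pc[i] = base_code(pattern[i]);
    if (pc[i] < 0) stop("pattern contains a non-ACGU symbol");
  }
  const int ns = seqs.size();
  IntegerMatrix out(ns, 2);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    std::vector<int> sc(L);
    for (int j = 0; j < L; ++j) sc[j] = base_code(s[j]);
    int best_pos = -1, best_mm = budget + 1;
    for (int p = 0; p + k <= L; ++p) {
      int mm = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (sc[p + j] < 0) { ok = false; break; }
        if (sc[p + j] != pc[j] && ++mm >= best_mm) { ok = false; break; }
      }
      if (ok && mm < best_mm) { best_mm = mm; best_pos = p; }
    }
    out(i, 0) = best_pos;
    out(i, 1) = best_pos >= 0 ? best_mm : NA_INTEGER;
  }
  return out;
}
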