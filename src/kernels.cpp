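#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman kernels. Residues arrive as 0-based integer
// codes indexing the substitution matrix; a gap of length L costs
// gap_open + L * gap_extend (BLAST convention).

static const int NEG_INF = -1000000;

// Score-only scan of one query against a delimiter-separated concatenated
// database. H and E are reset at each delimiter so alignments can never
// cross a sequence boundary; the per-segment maximum is recorded.
// Returns an integer vector with one best local score per segment.
// [[Rcpp::export]]
IntegerVector sw_scan_best(IntegerVector query, IntegerVector target,
                           IntegerMatrix matrix, int gap_open, int gap_extend,
                           int delim_code) {
  const int m = query.size();
  const int n = target.size();
  const int na = matrix.nrow();
  // flat row-major copy: row = target residue, col = query residue
  std::vector<int> M((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) M[(size_t)a * na + b] = matrix(a, b);
  std::vector<int> qc(m);
  for (int i = 0; i < m; ++i) qc[i] = query[i];

  const int goe = gap_open + gap_extend;
  const int ge = gap_extend;

  std::vector<int> H(m + 1, 0), E(m + 1, NEG_INF);
  std::vector<int> best;
  int segbest = 0;
  for (int j = 0; j < n; ++j) {
    const int tc = target[j];
    if (tc == delim_code) {
      best.push_back(segbest);
      segbest = 0;
      std::fill(H.begin(), H.end(), 0);
      std::fill(E.begin(), E.end(), NEG_INF);
      continue;
    }
    const int *row = &M[(size_t)tc * na];
    int diag = 0;      // H(i-1, j-1), starts as H(0, j-1) = 0
    int f = NEG_INF;   // F(i, j)
    int hup = 0;       // H(i-1, j)
    for (int i = 1; i <= m; ++i) {
      f = std::max(hup - goe, f - ge);
      const int e = std::max(H[i] - goe, E[i] - ge);
      int h = diag + row[qc[i - 1]];
      if (h < e) h = e;
      if (h < f) h = f;
      if (h < 0) h = 0;
      diag = H[i];
      H[i] = h;
      E[i] = e;
      hup = h;
      if (h > segbest) segbest = h;
    }
  }
  best.push_back(segbest);
  return wrap(best);
}

// Full Smith-Waterman with traceback between one query and one target,
// both small. Returns score plus 0-based half-open aligned intervals and
// alignment statistics. Tie-breaking is deterministic: the best-scoring
// cell with the smallest target, then query, end coordinate is chosen, and
// the traceback prefers diagonal moves over gaps.
struct AlnStats {
  int score, q_start, q_end, s_start, s_end;
  int align_len, matches, mismatches, gap_openings, gaps;
};

static AlnStats sw_pair(const int *q, int m, const int *t, int n,
                        const std::vector<int> &M, int na, int gap_open,
                        int gap_extend) {
  const int goe = gap_open + gap_extend;
  const int ge = gap_extend;
  const int w = n + 1;
  std::vector<int> H((size_t)(m + 1) * w, 0), E((size_t)(m + 1) * w, NEG_INF),
      F((size_t)(m + 1) * w, NEG_INF);
  int bscore = 0, bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    const int *row = &M[(size_t)t[j - 1] * na];
    for (int i = 1; i <= m; ++i) {
      const size_t c = (size_t)i * w + j;
      const int e = std::max(H[c - 1] - goe, E[c - 1] - ge);
      const int f = std::max(H[c - w] - goe, F[c - w] - ge);
      int h = H[c - w - 1] + row[q[i - 1]];
      if (h < e) h = e;
      if (h < f) h = f;
      if (h < 0) h = 0;
      H[c] = h;
      E[c] = e;
      F[c] = f;
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
  }
  AlnStats st{};
  st.score = bscore;
  if (bscore == 0) return st;  // empty alignment
  // traceback from (bi, bj) through the three-state recurrence
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in query), 2 = F
  int matches = 0, mismatches = 0, gap_open_n = 0, gaps = 0, alen = 0;
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * w + j;
    if (state == 0) {
      if (H[c] == 0) break;
      const int sub = M[(size_t)t[j - 1] * na + q[i - 1]];
      if (H[c] == H[c - w - 1] + sub) {
        ++alen;
        if (q[i - 1] == t[j - 1]) ++matches; else ++mismatches;
        --i; --j;
      } else if (H[c] == E[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // gap in query: consume target residue
      ++alen; ++gaps;
      const size_t c1 = c - 1;
      if (E[c] == H[c1] - goe) { ++gap_open_n; state = 0; }
      // else E[c] == E[c1] - ge, stay in E
      --j;
    } else {
      ++alen; ++gaps;
      const size_t cu = c - w;
      if (F[c] == H[cu] - goe) { ++gap_open_n; state = 0; }
      --i;
    }
  }
  st.q_start = i;
  st.q_end = bi;  // half-open: residues i..bi-1 of query (0-based)
  st.s_start = j;
  st.s_end = bj;
  st.align_len = alen;
  st.matches = matches;
  st.mismatches = mismatches;
  st.gap_openings = gap_open_n;
  st.gaps = gaps;
  return st;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector query, IntegerVector target,
                  IntegerMatrix matrix, int gap_open, int gap_extend) {
  const int na = matrix.nrow();
  std::vector<int> M((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) M[(size_t)a * na + b] = matrix(a, b);
  std::vector<int> q(query.begin(), query.end());
  std::vector<int> t(target.begin(), target.end());
  AlnStats st = sw_pair(q.data(), q.size(), t.data(), t.size(), M, na,
                        gap_open, gap_extend);
  return List::create(
      _["score"] = st.score, _["q_start"] = st.q_start, _["q_end"] = st.q_end,
      _["s_start"] = st.s_start, _["s_end"] = st.s_end,
      _["align_len"] = st.align_len, _["matches"] = st.matches,
      _["mismatches"] = st.mismatches, _["gap_openings"] = st.gap_openings,
      _["gaps"] = st.gaps);
}

// Align one query frame against many windows of the concatenated database
// in a single call. lo/hi are 0-based half-open window bounds into concat.
// Returns one row of statistics per window; coordinates are window-relative.
// [[Rcpp::export]]
IntegerMatrix sw_align_batch(IntegerVector query, IntegerVector concat,
                             IntegerVector lo, IntegerVector hi,
                             IntegerMatrix matrix, int gap_open,
                             int gap_extend) {
  const int na = matrix.nrow();
  std::vector<int> M((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) M[(size_t)a * na + b] = matrix(a, b);
  std::vector<int> q(query.begin(), query.end());
  const int nc = lo.size();
  IntegerMatrix out(nc, 10);
  std::vector<int> t;
  for (int k = 0; k < nc; ++k) {
    const int a = lo[k], b = hi[k];
    t.assign(concat.begin() + a, concat.begin() + b);
    AlnStats st = sw_pair(q.data(), q.size(), t.data(), t.size(), M, na,
                          gap_open, gap_extend);
    out(k, 0) = st.score;
    out(k, 1) = st.q_start;
    out(k, 2) = st.q_end;
    out(k, 3) = st.s_start;
    out(k, 4) = st.s_end;
    out(k, 5) = st.align_len;
    out(k, 6) = st.matches;
    out(k, 7) = st.mismatches;
    out(k, 8) = st.gap_openings;
    out(k, 9) = st.gaps;
  }
  colnames(out) = CharacterVector::create(
      "score", "q_start", "q_end", "s_start", "s_end", "align_len", "matches",
      "mismatches", "gap_openings", "gaps");
  return out;
}
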