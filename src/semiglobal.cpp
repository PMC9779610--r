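// Semi-global alignment kernels for germline segment assignment.
//
// Alignment model: the subject (germline segment) is consumed in full,
// end gaps on the query side are free (query prefix/suffix clipping costs
// nothing), interior gaps cost `gap` per base, matches/mismatches score
// `match`/`mismatch`. This equals Biostrings pairwiseAlignment with
// type = "local-global", gapOpening = 0 and gapExtension = |gap|, which
// the test suite uses as an independent oracle.

#include <Rcpp.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// score-only DP, one rolling row updated in place
static int sg_score(const char *q, int n, const char *s, int m, int match,
                    int mismatch, int gap) {
  std::vector<int> colv((size_t) m + 1);
  int *col = colv.data();
  col[0] = 0;
  for (int j = 1; j <= m; ++j) col[j] = col[j - 1] + gap;
  int best = col[m];
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    int prev = col[0];  // H[i-1][j-1]
    col[0] = 0;         // free query prefix
    int left = 0;       // H[i][j-1]
    for (int j = 1; j <= m; ++j) {
      const int up = col[j] + gap;
      const int dg = prev + (qc == s[j - 1] ? match : mismatch);
      prev = col[j];
      int v = dg > up ? dg : up;
      const int lf = left + gap;
      if (lf > v) v = lf;
      col[j] = v;
      left = v;
    }
    if (col[m] > best) best = col[m];  // free query suffix
  }
  return best;
}

// [[Rcpp::export(name = ".sg_score_matrix")]]
IntegerMatrix sg_score_matrix(CharacterVector queries,
                              CharacterVector subjects, int match,
                              int mismatch, int gap) {
  int nq = queries.size(), ns = subjects.size();
  IntegerMatrix out(nq, ns);
  for (int k = 0; k < ns; ++k) {
    const char *s = CHAR(STRING_ELT(subjects, k));
    int m = (int) std::strlen(s);
    for (int i = 0; i < nq; ++i) {
      const char *q = CHAR(STRING_ELT(queries, i));
      int n = (int) std::strlen(q);
      out(i, k) = sg_score(q, n, s, m, match, mismatch, gap);
    }
  }
  return out;
}

// Full DP with traceback; returns the 1-based query positions aligned to
// the requested 1-based subject positions (NA when that subject base is
// aligned to a gap in the query).
// [[Rcpp::export(name = ".sg_map_positions")]]
IntegerMatrix sg_map_positions(CharacterVector queries, std::string subject,
                               IntegerVector subject_pos, int match,
                               int mismatch, int gap) {
  int nq = queries.size();
  int m = (int) subject.size();
  int npos = subject_pos.size();
  IntegerMatrix out(nq, npos);
  const char *s = subject.c_str();

  std::vector<int> H;
  std::vector<unsigned char> T;
  for (int qi = 0; qi < nq; ++qi) {
    const char *q = CHAR(STRING_ELT(queries, qi));
    int n = (int) std::strlen(q);
    const size_t W = (size_t) m + 1;
    H.assign((size_t) (n + 1) * W, 0);
    T.assign((size_t) (n + 1) * W, 0);
    // traceback codes: 0 diag, 1 up (query base vs subject gap), 2 left
    // (subject base vs query gap), 3 free row start
    for (int i = 0; i <= n; ++i) T[(size_t) i * W] = 3;
    for (int j = 1; j <= m; ++j) {
      H[j] = H[j - 1] + gap;
      T[j] = 2;
    }
    for (int i = 1; i <= n; ++i) {
      const char qc = q[i - 1];
      int *row = H.data() + (size_t) i * W;
      const int *prow = row - W;
      unsigned char *trow = T.data() + (size_t) i * W;
      int left = row[0];
      for (int j = 1; j <= m; ++j) {
        const int dg = prow[j - 1] + (qc == s[j - 1] ? match : mismatch);
        const int up = prow[j] + gap;
        int v = dg;
        unsigned char t = 0;
        if (up > v) { v = up; t = 1; }
        const int lf = left + gap;
        if (lf > v) { v = lf; t = 2; }
        row[j] = v;
        trow[j] = t;
        left = v;
      }
    }
    // best end row (free query suffix); smallest i wins ties for a
    // deterministic placement
    int bi = 0, bscore = H[m];
    for (int i = 1; i <= n; ++i) {
      int v = H[(size_t) i * W + m];
      if (v > bscore) { bscore = v; bi = i; }
    }
    std::vector<int> qof((size_t) m + 1, NA_INTEGER);
    int i = bi, j = m;
    while (j > 0) {
      unsigned char t = T[(size_t) i * W + j];
      if (t == 3) break;
      if (t == 0) { qof[j] = i; --i; --j; }
      else if (t == 1) { --i; }
      else { --j; }
    }
    for (int k = 0; k < npos; ++k) {
      int p = subject_pos[k];
      out(qi, k) = (p >= 1 && p <= m) ? qof[p] : NA_INTEGER;
    }
  }
  return out;
}
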