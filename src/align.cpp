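#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Banded local alignment (Smith-Waterman restricted to a diagonal band) with
// affine gaps. Bases are integer-coded A=0,C=1,G=2,T=3; anything negative
// (e.g. N) mismatches everything. The band is centred on diagonal d0, where a
// cell (i, j) (1-based positions in query/subject) lies on diagonal j - i.
// A gap of length g costs gap_open + g * gap_ext (open charged once on top of
// the per-column extension, BLAST-style).
//
// Returns the best-scoring local alignment whose path stays inside the band:
// score, 1-based closed coordinates on query and subject, the number of
// identical columns ("matches") and total alignment columns (gaps included).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List banded_local_align(IntegerVector q, IntegerVector s, int d0, int band,
                        int match, int mismatch, int gap_open, int gap_ext) {
  const int n = q.size(), m = s.size();
  const int W = 2 * band + 1;
  // j = i + d0 + (k - band), k in [0, W)
  // DP over i = 0..n; store M (match/mismatch), X (gap in query, consumes
  // subject), Y (gap in subject, consumes query) plus traceback codes.
  std::vector<int> M((n + 1) * W, 0), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: 2 bits per matrix packed in a byte:
  //   tm: 0 = start here (local), 1 = from M diag, 2 = from X diag, 3 = from Y diag
  //   tx: 0 = open (from M left), 1 = extend (from X left)
  //   ty: 0 = open (from M up),  1 = extend (from Y up)
  std::vector<unsigned char> TM((n + 1) * W, 0), TX((n + 1) * W, 0),
      TY((n + 1) * W, 0);

  int best = 0, bi = -1, bk = -1; char bmat = 'M';
  const int go = gap_open + gap_ext;  // opening a gap of length 1

  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k < W; ++k) {
      const int j = i + d0 + (k - band);
      const int idx = i * W + k;
      if (i == 0 || j < 1 || j > m) {
        M[idx] = (j >= 0 && j <= m) ? 0 : NEG;
        X[idx] = NEG; Y[idx] = NEG;
        continue;
      }
      // M: diagonal move from (i-1, j-1) -> same k at row i-1
      const int pidx = (i - 1) * W + k;
      int sc = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      int fromM = M[pidx], fromX = X[pidx], fromY = Y[pidx];
      int bestPrev = 0; unsigned char tm = 0;
      if (fromM > bestPrev) { bestPrev = fromM; tm = 1; }
      if (fromX > bestPrev) { bestPrev = fromX; tm = 2; }
      if (fromY > bestPrev) { bestPrev = fromY; tm = 3; }
      int mval = bestPrev + sc;
      if (mval < 0) { mval = 0; tm = 0; }
      if (tm == 0 && mval > 0) tm = 0;  // fresh start on a positive match
      M[idx] = mval; TM[idx] = tm;

      // X: left move from (i, j-1) -> k-1 at same row
      if (k - 1 >= 0) {
        const int lidx = i * W + (k - 1);
        int xopen = (M[lidx] <= NEG / 2) ? NEG : M[lidx] - go;
        int xext = (X[lidx] <= NEG / 2) ? NEG : X[lidx] - gap_ext;
        if (xopen >= xext) { X[idx] = xopen; TX[idx] = 0; }
        else { X[idx] = xext; TX[idx] = 1; }
      }
      // Y: up move from (i-1, j) -> k+1 at row i-1
      if (k + 1 < W) {
        const int uidx = (i - 1) * W + (k + 1);
        int yopen = (M[uidx] <= NEG / 2) ? NEG : M[uidx] - go;
        int yext = (Y[uidx] <= NEG / 2) ? NEG : Y[uidx] - gap_ext;
        if (yopen >= yext) { Y[idx] = yopen; TY[idx] = 0; }
        else { Y[idx] = yext; TY[idx] = 1; }
      }
      if (M[idx] > best) { best = M[idx]; bi = i; bk = k; bmat = 'M'; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["columns"] = 0);

  // traceback from (bi, bk) in M
  int i = bi, k = bk; char mat = bmat;
  int matches = 0, columns = 0;
  int qe = bi, se = bi + d0 + (bk - band);
  int qs = qe, ss = se;
  bool done = false;
  while (!done && i >= 0 && k >= 0 && k < W) {
    const int idx = i * W + k;
    const int j = i + d0 + (k - band);
    if (mat == 'M') {
      ++columns;
      if (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ++matches;
      qs = i; ss = j;
      unsigned char t = TM[idx];
      if (t == 0) { done = true; break; }  // local start
      mat = (t == 1) ? 'M' : (t == 2) ? 'X' : 'Y';
      i -= 1;                              // diagonal: same k, row i-1
    } else if (mat == 'X') {
      ++columns;                           // gap column consuming subject
      unsigned char t = TX[idx];
      mat = (t == 0) ? 'M' : 'X';
      k -= 1;
    } else {                               // 'Y'
      ++columns;
      unsigned char t = TY[idx];
      mat = (t == 0) ? 'M' : 'Y';
      i -= 1; k += 1;
    }
  }

  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["matches"] = matches, _["columns"] = columns);
}
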