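#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh local alignment with affine gaps.
//
// Sequences arrive as 1-based integer indices into `submat`, so the same
// kernel serves nucleotide and amino-acid alphabets.  Gap cost for a gap of
// length L is gap_open + (L - 1) * gap_extend (both penalties <= 0; the
// first gapped column pays the opening penalty).
//
// Score rows are rolled (O(n) numeric memory); the traceback is kept as one
// packed byte per cell (bits 0-1: H came from stop/diagonal/F/E; bit 2: E
// opened here; bit 3: F opened here), so a transcript-against-mitogenome
// alignment stays within a few hundred MB.
//
// Traceback is deterministic: the best cell is the highest-scoring H cell
// with the smallest (i, j) on ties; within the traceback, ties prefer the
// diagonal, then the vertical (query-consuming, CIGAR 'I'), then the
// horizontal (target-consuming, CIGAR 'D') move.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector t, NumericMatrix submat,
              double gap_open, double gap_extend, bool score_only = false) {
  const long m = q.size(), n = t.size();
  const double NEG = -1e18;

  std::vector<double> Hup(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fup(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<unsigned char> dir;
  if (!score_only) dir.assign((size_t)m * (size_t)n, 0);

  double best = 0.0;
  long bi = 0, bj = 0;

  for (long i = 1; i <= m; ++i) {
    double Eleft = NEG;        // E[i][j-1]
    double Hleft = 0.0;        // H[i][j-1]
    Hcur[0] = 0.0;
    for (long j = 1; j <= n; ++j) {
      unsigned char cell = 0;

      double e_open = Hleft + gap_open;
      double e_ext  = Eleft + gap_extend;
      double E;
      if (e_open >= e_ext) { E = e_open; cell |= 4; }
      else                 { E = e_ext; }

      double f_open = Hup[j] + gap_open;
      double f_ext  = Fup[j] + gap_extend;
      double F;
      if (f_open >= f_ext) { F = f_open; cell |= 8; }
      else                 { F = f_ext; }

      double diag = Hup[j - 1] + submat(q[i - 1] - 1, t[j - 1] - 1);

      double h = 0.0; unsigned char d = 0;
      if (diag > h) { h = diag; d = 1; }
      if (F > h)    { h = F;    d = 2; }
      if (E > h)    { h = E;    d = 3; }
      cell |= d;
      if (!score_only) dir[(size_t)(i - 1) * n + (j - 1)] = cell;

      Hcur[j] = h; Fcur[j] = F;
      Eleft = E; Hleft = h;

      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hup, Hcur);
    std::swap(Fup, Fcur);
  }

  if (best <= 0.0 || score_only) {
    return List::create(_["score"] = best,
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["target_start"] = 0, _["target_end"] = 0,
                        _["cigar"] = "", _["n_match"] = 0, _["n_col"] = 0);
  }

  // Traceback from (bi, bj); state 0 = in H, 2 = in F, 3 = in E.
  std::string ops;
  long i = bi, j = bj;
  int state = 0, n_match = 0;
  while (true) {
    const unsigned char cell = dir[(size_t)(i - 1) * n + (j - 1)];
    if (state == 0) {
      const unsigned char d = cell & 3;
      if (d == 0) break;
      if (d == 1) {
        ops.push_back('M');
        if (q[i - 1] == t[j - 1]) ++n_match;
        --i; --j;
        if (i == 0 || j == 0) break;
      } else if (d == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {            // gap in target, consumes query
      ops.push_back('I');
      if (cell & 8) state = 0;
      --i;
      if (i == 0) break;
    } else {                            // gap in query, consumes target
      ops.push_back('D');
      if (cell & 4) state = 0;
      --j;
      if (j == 0) break;
    }
  }

  // ops is reversed; compress to CIGAR.
  std::string cigar;
  int run = 0; char cur = 0;
  for (long k = (long)ops.size() - 1; k >= 0; --k) {
    if (ops[k] == cur) { ++run; }
    else {
      if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }
      cur = ops[k]; run = 1;
    }
  }
  if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }

  return List::create(_["score"] = best,
                      _["query_start"] = (int)i, _["query_end"] = (int)bi,
                      _["target_start"] = (int)j, _["target_end"] = (int)bj,
                      _["cigar"] = cigar,
                      _["n_match"] = n_match,
                      _["n_col"] = (int)ops.size());
}
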