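#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh), local (Smith-Waterman) or global
// (Needleman-Wunsch). A gap of length L costs open + L * ext.
//
// Sequences arrive as integer codes (0-based indices into the alphabet of the
// scoring matrix). Rows of the DP correspond to `a` (query), columns to `b`
// (subject). Traceback ties are resolved diagonal > up > left, where "up"
// consumes a query residue (gap in subject) and "left" consumes a subject
// residue (gap in query). The start cell for local traceback is the
// maximum-score cell with smallest i, then smallest j.
//
// One byte of traceback per cell:
//   bits 0-1: source of H (0 = stop/origin, 1 = diag, 2 = E/up, 3 = F/left)
//   bit 2   : E extended from E (else opened from H)
//   bit 3   : F extended from F (else opened from H)
//
// `band`: if > 0, only cells with |i - j - shift| <= band are computed
// (others stay -inf / unreachable). Callers must ensure the optimum lies in
// the band; used for near-collinear long sequences.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(IntegerVector a, IntegerVector b, NumericMatrix S,
               double gap_open, double gap_ext, bool global,
               int band = 0, int band_shift = 0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double gopen = gap_open + gap_ext;  // cost of first gap residue

  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<double> Hprev(m + 1), Hcur(m + 1), Eprev(m + 1), Ecur(m + 1),
      Fcur(m + 1);

  // row 0
  for (int j = 0; j <= m; ++j) {
    Hprev[j] = global ? (j == 0 ? 0.0 : -(gap_open + gap_ext * j)) : 0.0;
    Eprev[j] = NEG_INF;
    if (global && j > 0) tb[j] = 3;  // left along row 0
  }

  double best = global ? NEG_INF : 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      jlo = std::max(1, i - band_shift - band);
      jhi = std::min(m, i - band_shift + band);
      if (jlo > jhi) { jlo = 1; jhi = 0; }
    }
    Hcur[0] = global ? -(gap_open + gap_ext * i) : 0.0;
    Ecur[0] = NEG_INF;
    Fcur[0] = NEG_INF;
    if (global) tb[(size_t)i * (m + 1)] = 2;  // up along column 0
    // band boundary cells must not leak values from earlier rows
    if (jlo > 1) {
      Hcur[jlo - 1] = NEG_INF; Fcur[jlo - 1] = NEG_INF;
      Ecur[jlo - 1] = NEG_INF;
    }
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t t = 0;
      // E: gap in subject (vertical move, consumes a[i-1])
      double e_open = Hprev[j] - gopen;
      double e_ext  = Eprev[j] - gap_ext;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; t |= 4; }
      // F: gap in query (horizontal move, consumes b[j-1])
      double f_open = Hcur[j - 1] - gopen;
      double f_ext  = Fcur[j - 1] - gap_ext;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; t |= 8; }
      // H
      double d = Hprev[j - 1] + S(a[i - 1], b[j - 1]);
      double h; uint8_t src;
      // tie preference: diag > up(E) > left(F)
      if (d >= e && d >= f) { h = d; src = 1; }
      else if (e >= f)      { h = e; src = 2; }
      else                  { h = f; src = 3; }
      if (!global && h < 0) { h = 0; src = 0; }
      t |= src;
      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      tb[(size_t)i * (m + 1) + j] = t;
      if (!global && h > best) { best = h; bi = i; bj = j; }
    }
    if (jhi < m) { Hcur[jhi + 1] = NEG_INF; Ecur[jhi + 1] = NEG_INF; }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (global) {
    best = Hprev[m];
    bi = n; bj = m;
  }

  if (!global && best <= 0.0) {
    return List::create(_["score"] = 0.0, _["empty"] = true);
  }

  // traceback
  std::vector<int> qa, sa;  // aligned codes, -1 = gap
  int i = bi, j = bj;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  while (true) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;                      // local origin
      if (src == 1) {
        qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
        --i; --j;
        if (global && i == 0 && j == 0) break;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {                    // E: up
      qa.push_back(a[i - 1]); sa.push_back(-1);
      bool ext = (t & 4) != 0;
      --i;
      if (!ext) state = 0;
      if (global && i == 0 && j == 0) break;
      if (i == 0) {                             // global row-0 tail
        while (j > 0) { qa.push_back(-1); sa.push_back(b[j - 1]); --j; }
        break;
      }
    } else {                                    // F: left
      qa.push_back(-1); sa.push_back(b[j - 1]);
      bool ext = (t & 8) != 0;
      --j;
      if (!ext) state = 0;
      if (global && i == 0 && j == 0) break;
      if (j == 0) {
        while (i > 0) { qa.push_back(a[i - 1]); sa.push_back(-1); --i; }
        break;
      }
    }
    if (!global && (i == 0 || j == 0)) break;
    if (global && i == 0 && j == 0) break;
    if (global && i == 0) { while (j > 0) { qa.push_back(-1); sa.push_back(b[j - 1]); --j; } break; }
    if (global && j == 0) { while (i > 0) { qa.push_back(a[i - 1]); sa.push_back(-1); --i; } break; }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(
      _["score"] = best, _["empty"] = false,
      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
      _["s_aln"] = IntegerVector(sa.begin(), sa.end()),
      _["q_start"] = i, _["q_end"] = bi,     // 0-based half-open on a
      _["s_start"] = j, _["s_end"] = bj);
}
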