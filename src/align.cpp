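#include <Rcpp.h>
#include <vector>
#include <string>
#include <cfloat>
using namespace Rcpp;

// Affine-gap (Gotoh) pairwise DNA alignment with optional banding and optional
// free end gaps on the second sequence (fitting alignment, used to place a
// full-length query inside a genomic window).
//
// Gap model: a run of L gap columns costs gap_open + (L - 1) * gap_ext, i.e.
// gap_open is charged for the first gap base and gap_ext for each additional
// one. Linear gap scoring is obtained with gap_ext == gap_open.
//
// 'N' mismatches every base, including another 'N'.

static inline double subst(char a, char b, double match, double mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

// traceback states
static const unsigned char FROM_H = 0; // diagonal into H
static const unsigned char FROM_E = 1; // vertical (gap in b, consumes a)
static const unsigned char FROM_F = 2; // horizontal (gap in a, consumes b)

// ex0/ex1 (0-based half-open, ex1 <= ex0 disables) mark a span of `a` whose
// alignment columns are excluded from the reported flank_* statistics: when a
// query carries a tandem-repeat tract whose length varies between samples,
// identity/coverage acceptance must be judged on the flanks, not on the
// length polymorphism itself. Gap-in-a columns at or inside the span borders
// count as span columns (extra repeat copies in b).

// [[Rcpp::export]]
List c_align_pair(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext,
                  bool fit_b, int band, int ex0, int ex1) {
  const int na = (int) a.size();
  const int nb = (int) b.size();
  if (na == 0 || nb == 0) stop("empty sequence in alignment");
  if ((double) (na + 1) * (double) (nb + 1) > 1.0e7)
    stop("alignment problem too large (%d x %d)", na, nb);

  const double NEG = -DBL_MAX / 4.0;
  const int W = nb + 1;
  std::vector<double> H((size_t)(na + 1) * W, NEG);
  std::vector<double> E((size_t)(na + 1) * W, NEG);
  std::vector<double> F((size_t)(na + 1) * W, NEG);
  // pointer matrices: for H, which matrix produced it; for E/F, whether the
  // gap was opened (came from H) or extended.
  std::vector<unsigned char> PH((size_t)(na + 1) * W, 0);
  std::vector<unsigned char> PE((size_t)(na + 1) * W, 0);
  std::vector<unsigned char> PF((size_t)(na + 1) * W, 0);

  auto jlo = [&](int i) -> int {
    if (band <= 0) return 0;
    double diag = na > 0 ? (double) i * nb / na : 0.0;
    int lo = (int) (diag - band);
    return lo < 0 ? 0 : lo;
  };
  auto jhi = [&](int i) -> int {
    if (band <= 0) return nb;
    double diag = na > 0 ? (double) i * nb / na : 0.0;
    int hi = (int) (diag + band);
    return hi > nb ? nb : hi;
  };

  H[0] = 0.0;
  for (int j = 1; j <= jhi(0); ++j) {
    if (fit_b) {
      H[j] = 0.0;                       // free leading gap in b
    } else {
      F[j] = -(gap_open + (j - 1) * gap_ext);
      PF[j] = (j == 1) ? FROM_H : FROM_F;
      H[j] = F[j];
      PH[j] = FROM_F;
    }
  }
  for (int i = 1; i <= na; ++i) {
    size_t row = (size_t) i * W, prow = (size_t)(i - 1) * W;
    int lo = jlo(i), hi = jhi(i);
    if (lo == 0) {
      E[row] = -(gap_open + (i - 1) * gap_ext);
      PE[row] = (i == 1) ? FROM_H : FROM_E;
      H[row] = E[row];
      PH[row] = FROM_E;
    }
    for (int j = (lo > 1 ? lo : 1); j <= hi; ++j) {
      // E: gap in b (vertical)
      double eo = (H[prow + j] > NEG / 2) ? H[prow + j] - gap_open : NEG;
      double ee = (E[prow + j] > NEG / 2) ? E[prow + j] - gap_ext : NEG;
      if (eo >= ee) { E[row + j] = eo; PE[row + j] = FROM_H; }
      else          { E[row + j] = ee; PE[row + j] = FROM_E; }
      // F: gap in a (horizontal)
      double fo = (H[row + j - 1] > NEG / 2) ? H[row + j - 1] - gap_open : NEG;
      double fe = (F[row + j - 1] > NEG / 2) ? F[row + j - 1] - gap_ext : NEG;
      if (fo >= fe) { F[row + j] = fo; PF[row + j] = FROM_H; }
      else          { F[row + j] = fe; PF[row + j] = FROM_F; }
      // H
      double dg = (H[prow + j - 1] > NEG / 2)
        ? H[prow + j - 1] + subst(a[i - 1], b[j - 1], match, mismatch) : NEG;
      double best = dg; unsigned char pb = FROM_H;
      if (E[row + j] > best) { best = E[row + j]; pb = FROM_E; }
      if (F[row + j] > best) { best = F[row + j]; pb = FROM_F; }
      H[row + j] = best; PH[row + j] = pb;
    }
  }

  // end cell
  int jend = nb;
  size_t lastrow = (size_t) na * W;
  if (fit_b) {
    double best = NEG;
    for (int j = jlo(na); j <= jhi(na); ++j)
      if (H[lastrow + j] > best) { best = H[lastrow + j]; jend = j; }
  }
  double score = H[lastrow + jend];
  if (score < NEG / 2) stop("band too narrow: no alignment path");

  // traceback from (na, jend) to row 0
  int i = na, j = jend;
  unsigned char state = FROM_H;
  const bool has_ex = ex1 > ex0;
  long columns = 0, matches = 0, a_aligned = 0;
  long fcolumns = 0, fmatches = 0, f_aligned = 0;   // outside excluded span
  int b_end = jend, b_start = jend;
  IntegerVector map_a(na, NA_INTEGER);
  while (i > 0 || (!fit_b && j > 0)) {
    if (i == 0 && fit_b) break;
    size_t row = (size_t) i * W;
    if (state == FROM_H) {
      unsigned char p = PH[row + j];
      if (p == FROM_E) { state = FROM_E; continue; }
      if (p == FROM_F) { state = FROM_F; continue; }
      // diagonal
      bool in_ex = has_ex && (i - 1) >= ex0 && (i - 1) < ex1;
      bool is_match = (a[i - 1] == b[j - 1] && a[i - 1] != 'N');
      columns++;
      if (is_match) matches++;
      a_aligned++;
      if (!in_ex) {
        fcolumns++;
        if (is_match) fmatches++;
        f_aligned++;
      }
      map_a[i - 1] = j;        // 1-based b position
      b_start = j - 1;
      i--; j--;
    } else if (state == FROM_E) {
      unsigned char p = PE[row + j];
      bool in_ex = has_ex && (i - 1) >= ex0 && (i - 1) < ex1;
      columns++;
      if (!in_ex) fcolumns++;
      i--;
      state = (p == FROM_H) ? FROM_H : FROM_E;
    } else { // FROM_F
      unsigned char p = PF[row + j];
      bool in_ex = has_ex && i >= ex0 && i <= ex1;
      columns++;
      if (!in_ex) fcolumns++;
      b_start = j - 1;
      j--;
      state = (p == FROM_H) ? FROM_H : FROM_F;
    }
  }
  if (!fit_b) { b_start = 0; b_end = nb; }

  return List::create(
    _["score"] = score,
    _["columns"] = (double) columns,
    _["matches"] = (double) matches,
    _["a_aligned"] = (double) a_aligned,
    _["flank_columns"] = (double) fcolumns,
    _["flank_matches"] = (double) fmatches,
    _["flank_aligned"] = (double) f_aligned,
    _["b_start"] = b_start,          // 0-based half-open aligned span of b
    _["b_end"] = b_end,
    _["map_a"] = map_a);             // per a-base: aligned b position (1-based) or NA
}
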