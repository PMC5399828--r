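#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_ext (same convention as
// Biostrings::pairwiseAlignment).  Among all maximum-score alignments the
// one with the most identical columns is chosen, and among those the one
// with the fewest total columns, so identity = matches / columns is a
// deterministic function of the optimum (no traceback needed).

struct Cell {
  double score;
  int matches;
  int cols; // total alignment columns (maximize -cols)
};

static inline bool lex_less(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score < b.score;
  if (a.matches != b.matches) return a.matches < b.matches;
  return a.cols > b.cols; // fewer columns is better
}

static inline Cell lex_max(const Cell &a, const Cell &b) {
  return lex_less(a, b) ? b : a;
}

static inline Cell step(const Cell &c, double ds, int dm) {
  Cell r = {c.score + ds, c.matches + dm, c.cols + 1};
  return r;
}

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".gotoh_identity_cpp")]]
NumericVector gotoh_identity_cpp(std::string a, std::string b,
                                 double match = 1.0, double mismatch = -1.0,
                                 double gap_open = 5.0, double gap_ext = 1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const Cell none = {NEG_INF, 0, 0};

  // Rolling rows: M = align a[i] with b[j]; X = gap in b (consume a);
  // Y = gap in a (consume b).
  std::vector<Cell> Mp(m + 1), Xp(m + 1), Yp(m + 1), Mc(m + 1), Xc(m + 1), Yc(m + 1);

  Mp[0] = {0.0, 0, 0};
  Xp[0] = none;
  Yp[0] = none;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = none;
    Xp[j] = none;
    Yp[j] = {-(gap_open + gap_ext * j), 0, j};
  }
  // Row 0 uses Yp for leading gaps in a; swap naming: treat Yp as "gap in a".

  for (int i = 1; i <= n; ++i) {
    Mc[0] = none;
    Yc[0] = none;
    Xc[0] = {-(gap_open + gap_ext * i), 0, i};
    for (int j = 1; j <= m; ++j) {
      const bool eq = (a[i - 1] == b[j - 1]);
      const double s = eq ? match : mismatch;
      // M: diagonal from any state
      Cell best = lex_max(Mp[j - 1], lex_max(Xp[j - 1], Yp[j - 1]));
      Mc[j] = (best.score <= NEG_INF / 2) ? none : step(best, s, eq ? 1 : 0);
      // X: gap in b, consume a[i] (vertical)
      Cell open_x = lex_max(Mp[j], Yp[j]);
      Cell from_open = (open_x.score <= NEG_INF / 2)
                           ? none
                           : step(open_x, -(gap_open + gap_ext), 0);
      Cell from_ext =
          (Xp[j].score <= NEG_INF / 2) ? none : step(Xp[j], -gap_ext, 0);
      Xc[j] = lex_max(from_open, from_ext);
      // Y: gap in a, consume b[j] (horizontal)
      Cell open_y = lex_max(Mc[j - 1], Xc[j - 1]);
      Cell yo = (open_y.score <= NEG_INF / 2)
                    ? none
                    : step(open_y, -(gap_open + gap_ext), 0);
      Cell ye =
          (Yc[j - 1].score <= NEG_INF / 2) ? none : step(Yc[j - 1], -gap_ext, 0);
      Yc[j] = lex_max(yo, ye);
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }

  Cell fin = lex_max(Mp[m], lex_max(Xp[m], Yp[m]));
  return NumericVector::create(
      _["identity"] = (double)fin.matches / (double)fin.cols,
      _["score"] = fin.score, _["matches"] = (double)fin.matches,
      _["columns"] = (double)fin.cols);
}
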