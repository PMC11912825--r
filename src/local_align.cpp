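#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap (Gotoh) local alignment between a and b.
//
// Optimises lexicographically: best score first, then the largest number of
// aligned columns among score-optimal alignments. A gap of length k costs
// gap_open + k * gap_ext. When self_exclude is true the match/mismatch move
// into cell (i, i) is forbidden, so an alignment can never pair position i
// of a with position i of b -- this removes the trivial main-diagonal
// self-hit when a sequence is compared against itself.
//
// Returns list(score, length): length is the number of aligned columns
// (including gapped columns) of a best-scoring alignment; 0 if no positive-
// scoring alignment exists.
// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string a, std::string b,
                     double match = 1.0, double mismatch = -3.0,
                     double gap_open = 5.0, double gap_ext = 2.0,
                     bool self_exclude = false) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // rolling rows; each cell carries (score, columns)
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG), F(m + 1, NEG);
  std::vector<double> Hl(m + 1, 0.0), El(m + 1, 0.0), Fl(m + 1, 0.0);
  std::vector<double> Hp(m + 1, 0.0), Ep(m + 1, NEG), Fp(m + 1, NEG);
  std::vector<double> Hlp(m + 1, 0.0), Elp(m + 1, 0.0), Flp(m + 1, 0.0);

  double best = 0.0, best_len = 0.0;

  for (int i = 1; i <= n; ++i) {
    H[0] = 0.0; Hl[0] = 0.0; E[0] = NEG; El[0] = 0.0; F[0] = NEG; Fl[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (consume b[j]); from H (open) or E (extend) on the left
      double e_open = H[j - 1] - gap_open - gap_ext;
      double e_ext  = E[j - 1] - gap_ext;
      if (e_open > e_ext || (e_open == e_ext && Hl[j - 1] + 1 >= El[j - 1] + 1)) {
        E[j] = e_open; El[j] = Hl[j - 1] + 1;
      } else {
        E[j] = e_ext;  El[j] = El[j - 1] + 1;
      }
      // F: gap in b (consume a[i]); from previous row
      double f_open = Hp[j] - gap_open - gap_ext;
      double f_ext  = Fp[j] - gap_ext;
      if (f_open > f_ext || (f_open == f_ext && Hlp[j] + 1 >= Flp[j] + 1)) {
        F[j] = f_open; Fl[j] = Hlp[j] + 1;
      } else {
        F[j] = f_ext;  Fl[j] = Flp[j] + 1;
      }
      // diagonal
      double d = NEG, dl = 0.0;
      if (!(self_exclude && i == j)) {
        double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        d = Hp[j - 1] + s;
        dl = Hlp[j - 1] + 1;
      }
      // H = max(0, d, E, F), tie-break on longer alignment
      double h = 0.0, hl = 0.0;
      if (d > h || (d == h && dl > hl)) { h = d; hl = dl; }
      if (E[j] > h || (E[j] == h && El[j] > hl)) { h = E[j]; hl = El[j]; }
      if (F[j] > h || (F[j] == h && Fl[j] > hl)) { h = F[j]; hl = Fl[j]; }
      H[j] = h; Hl[j] = hl;
      if (h > best || (h == best && hl > best_len)) { best = h; best_len = hl; }
    }
    std::swap(H, Hp); std::swap(Hl, Hlp);
    std::swap(E, Ep); std::swap(El, Elp);
    std::swap(F, Fp); std::swap(Fl, Flp);
  }
  if (best <= 0.0) { best = 0.0; best_len = 0.0; }
  return List::create(_["score"] = best, _["length"] = best_len);
}
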