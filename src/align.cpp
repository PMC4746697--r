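#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Alignment kernels. Sequences arrive as uppercase DNA-alphabet strings
// (U already folded to T by the readers). N never matches or pairs.

static inline bool dna_eq(char a, char b) { return a == b && a != 'N'; }

// Does base a (on the top strand, 5'->3') anneal with base b (bottom strand,
// given as its forward-sense character) in an antiparallel duplex?
// Watson-Crick plus optional G:U wobble (G:T in the DNA alphabet).
static inline bool anneal_pair(char a, char b, bool gu) {
  switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A' || (gu && b == 'G');
    case 'G': return b == 'C' || (gu && b == 'T');
    case 'C': return b == 'G';
    default:  return false;
  }
}

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// gap_open and gap_extend are negative; a gap of length L scores
// gap_open + L * gap_extend. Returns the single best local alignment with
// deterministic tie-breaking (first maximum in row-major scan; traceback
// prefers diagonal over vertical over horizontal).
// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string a, std::string b, double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // moves: H: 0 stop, 1 diag, 2 from E (gap in a / consumes b), 3 from F
  //        E/F: 0 opened from H, 1 extended
  std::vector<signed char> MH((n + 1) * W, 0), ME((n + 1) * W, 0), MF((n + 1) * W, 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double e_open = H[ij - 1] + gap_open + gap_extend;
      double e_ext  = E[ij - 1] + gap_extend;
      E[ij] = (e_open >= e_ext) ? e_open : e_ext;
      ME[ij] = (e_open >= e_ext) ? 0 : 1;
      double f_open = H[ij - W] + gap_open + gap_extend;
      double f_ext  = F[ij - W] + gap_extend;
      F[ij] = (f_open >= f_ext) ? f_open : f_ext;
      MF[ij] = (f_open >= f_ext) ? 0 : 1;
      double diag = H[ij - W - 1] +
        (dna_eq(a[i - 1], b[j - 1]) ? match : mismatch);
      double h = 0.0; signed char mv = 0;
      if (diag > h) { h = diag; mv = 1; }
      if (F[ij] > h) { h = F[ij]; mv = 3; }
      if (E[ij] > h) { h = E[ij]; mv = 2; }
      H[ij] = h; MH[ij] = (h <= 0.0) ? 0 : mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int n_cols = 0, n_match = 0;
  int longest_block = 0, longest_perfect = 0, cur_block = 0, cur_perfect = 0;
  int i = bi, j = bj;
  if (best > 0.0) {
    int state = 0; // 0 = H, 1 = E, 2 = F
    for (;;) {
      const int ij = i * W + j;
      if (state == 0) {
        signed char mv = MH[ij];
        if (mv == 0) break;
        if (mv == 1) {
          ++n_cols; ++cur_block;
          if (dna_eq(a[i - 1], b[j - 1])) { ++n_match; ++cur_perfect; }
          else cur_perfect = 0;
          if (cur_block > longest_block) longest_block = cur_block;
          if (cur_perfect > longest_perfect) longest_perfect = cur_perfect;
          --i; --j;
        } else if (mv == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        ++n_cols; cur_block = 0; cur_perfect = 0;
        signed char mv = ME[ij];
        --j;
        state = (mv == 1) ? 1 : 0;
      } else {
        ++n_cols; cur_block = 0; cur_perfect = 0;
        signed char mv = MF[ij];
        --i;
        state = (mv == 1) ? 2 : 0;
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = (best > 0.0) ? i + 1 : NA_INTEGER,
    _["a_end"] = (best > 0.0) ? bi : NA_INTEGER,
    _["b_start"] = (best > 0.0) ? j + 1 : NA_INTEGER,
    _["b_end"] = (best > 0.0) ? bj : NA_INTEGER,
    _["n_cols"] = n_cols,
    _["n_match"] = n_match,
    _["longest_block"] = longest_block,
    _["longest_perfect"] = longest_perfect);
}

// Inter-molecular duplex alignment by base-pair maximization: local DP over
// the top-strand window a (5'->3') and the reversed bottom-strand window br
// (so pairing is monotone). Objective: (#paired columns) - lambda * (#unpaired
// interior nucleotides). No mismatch column exists: a non-pairing opposition
// costs two bubble columns (one per strand). Returns the paired columns of
// the best region; bubbles and perfect segments are derived in R.
// [[Rcpp::export(name = ".duplex_local")]]
List duplex_local(std::string a, std::string br, double lambda, bool gu) {
  const int n = (int)a.size(), m = (int)br.size();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0);
  std::vector<signed char> MV((n + 1) * W, 0); // 0 stop, 1 pair, 2 up, 3 left

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double h = 0.0; signed char mv = 0;
      if (anneal_pair(a[i - 1], br[j - 1], gu)) {
        double d = H[ij - W - 1] + 1.0;
        if (d > h) { h = d; mv = 1; }
      }
      double up = H[ij - W] - lambda;
      if (up > h) { h = up; mv = 2; }
      double lf = H[ij - 1] - lambda;
      if (lf > h) { h = lf; mv = 3; }
      H[ij] = h; MV[ij] = (h <= 0.0) ? 0 : mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> pa, pb;
  int i = bi, j = bj;
  while (best > 0.0) {
    signed char mv = MV[i * W + j];
    if (mv == 0) break;
    if (mv == 1) { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (mv == 2) --i;
    else --j;
  }
  const int np = (int)pa.size();
  IntegerMatrix pairs(np, 2);
  for (int k = 0; k < np; ++k) { // reverse to ascending order
    pairs(k, 0) = pa[np - 1 - k];
    pairs(k, 1) = pb[np - 1 - k];
  }
  colnames(pairs) = CharacterVector::create("pos_a", "pos_br");
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
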