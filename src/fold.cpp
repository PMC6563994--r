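#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Base coding: A=0, C=1, G=2, U/T=3, other=-1.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// Pair coding matching the shipped stack table row/column order:
// AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 when not pairable.
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;  // A-U
  if (a == 3 && b == 0) return 1;  // U-A
  if (a == 1 && b == 2) return 2;  // C-G
  if (a == 2 && b == 1) return 3;  // G-C
  if (a == 2 && b == 3) return 4;  // G-U
  if (a == 3 && b == 2) return 5;  // U-G
  return -1;
}

static const double INF = std::numeric_limits<double>::infinity();

// Single stem-loop folding by interval dynamic programming.
//
// E(i,j) is the best (lowest) energy of a stem-loop closed by pair (i,j):
// either a terminal hairpin loop (>= min_loop unpaired nt, constant
// penalty), or an inner pair (k,l) reached through a stack (k=i+1, l=j-1,
// energy from the nearest-neighbor table) or through a bulge/interior loop
// (positive penalty, linear in the number of unpaired nucleotides, each
// side capped at max_intr). Multibranch structures are outside the model:
// every admissible structure is one nested run of pairs.
// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, NumericMatrix stack,
                      double hairpin_pen, double intr_open,
                      double intr_per_nt, int max_intr, int min_loop) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);

  std::vector<std::vector<double> > E(n, std::vector<double>(n, INF));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, -1));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = (s[i] >= 0 && s[j] >= 0) ? pair_code(s[i], s[j]) : -1;
      if (pij < 0) continue;
      double best = INF;
      if (j - i - 1 >= min_loop) best = hairpin_pen;
      int kmax = std::min(i + 1 + max_intr, j - min_loop - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + min_loop + 1, j - 1 - max_intr);
        for (int l = j - 1; l >= lmin; --l) {
          if (E[k][l] == INF) continue;
          double cost;
          if (k == i + 1 && l == j - 1) {
            int pkl = pair_code(s[k], s[l]);
            cost = stack(pij, pkl);
          } else {
            cost = intr_open + intr_per_nt * ((k - i - 1) + (j - l - 1));
          }
          if (cost + E[k][l] < best) best = cost + E[k][l];
        }
      }
      E[i][j] = best;
      P[i][j] = 1;
    }
  }

  // Global optimum over all closing pairs.
  double dG = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + min_loop + 1; j < n; ++j)
      if (E[i][j] < dG) { dG = E[i][j]; bi = i; bj = j; }

  std::string db(n, '.');
  std::vector<int> pi_out, pj_out;
  if (bi >= 0) {
    // Traceback: re-derive the choice made at each closed pair.
    int i = bi, j = bj;
    while (true) {
      pi_out.push_back(i + 1);
      pj_out.push_back(j + 1);
      db[i] = '(';
      db[j] = ')';
      double target = E[i][j];
      int pij = pair_code(s[i], s[j]);
      if (j - i - 1 >= min_loop &&
          std::abs(target - hairpin_pen) < 1e-9) break;
      bool found = false;
      int kmax = std::min(i + 1 + max_intr, j - min_loop - 1);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int lmin = std::max(k + min_loop + 1, j - 1 - max_intr);
        for (int l = j - 1; l >= lmin && !found; --l) {
          if (E[k][l] == INF) continue;
          double cost;
          if (k == i + 1 && l == j - 1)
            cost = stack(pij, pair_code(s[k], s[l]));
          else
            cost = intr_open + intr_per_nt * ((k - i - 1) + (j - l - 1));
          if (std::abs(cost + E[k][l] - target) < 1e-9) {
            i = k; j = l; found = true;
          }
        }
      }
      if (!found) break;  // numeric safety net; terminal hairpin
    }
  } else {
    dG = 0.0;
  }

  return List::create(_["dG"] = dG, _["dotbracket"] = db,
                      _["pair_i"] = wrap(pi_out), _["pair_j"] = wrap(pj_out));
}

// ---- miRanda-style duplex alignment -------------------------------------

// Residue-pair score between a miRNA base (read 3'->5') and a UTR window
// base (5'->3'): Watson-Crick complement scores `match`, G:U wobble scores
// `wobble`, anything else `mismatch`. Positions whose miRNA 5'-based index
// lies in [seed_start, seed_end] are scaled by seed_scale.
struct DuplexScheme {
  double match, mismatch, wobble, gap_open, gap_extend, seed_scale;
  int seed_start, seed_end;
};

static inline double pair_score(int a, int b, const DuplexScheme& sc,
                                int mirna_pos5, int* type) {
  int pc = pair_code(a, b);
  double v;
  if (pc == 0 || pc == 1 || pc == 2 || pc == 3) { v = sc.match; *type = 2; }
  else if (pc == 4 || pc == 5) { v = sc.wobble; *type = 1; }
  else { v = sc.mismatch; *type = 0; }
  if (mirna_pos5 >= sc.seed_start && mirna_pos5 <= sc.seed_end)
    v *= sc.seed_scale;
  return v;
}

// Affine-gap local alignment (Gotoh) of the reversed miRNA against a UTR
// window. Returns the best score; when `traceback` is true also the list of
// aligned residue pairs. Gap of length k costs gap_open + (k-1)*gap_extend
// (both negative).
static double duplex_align_core(const std::vector<int>& r,  /* reversed miRNA */
                                const std::vector<int>& w,
                                int mlen, const DuplexScheme& sc,
                                bool traceback,
                                std::vector<int>* out_mpos,
                                std::vector<int>* out_wpos,
                                std::vector<int>* out_type) {
  int m = (int) r.size(), n = (int) w.size();
  if (m == 0 || n == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<std::vector<double> > M(m + 1, std::vector<double>(n + 1, NEG)),
      X(m + 1, std::vector<double>(n + 1, NEG)),
      Y(m + 1, std::vector<double>(n + 1, NEG));
  for (int a = 0; a <= m; ++a) M[a][0] = NEG;
  for (int b = 0; b <= n; ++b) M[0][b] = NEG;
  double best = 0.0;
  int ba = -1, bb = -1;
  int dummy;
  for (int a = 1; a <= m; ++a) {
    int pos5 = mlen - (a - 1);  // miRNA position counted from its 5' end
    for (int b = 1; b <= n; ++b) {
      int type;
      double s = pair_score(r[a - 1], w[b - 1], sc, pos5, &type);
      double prev = 0.0;  // local alignment: may start fresh
      if (M[a - 1][b - 1] > prev) prev = M[a - 1][b - 1];
      if (X[a - 1][b - 1] > prev) prev = X[a - 1][b - 1];
      if (Y[a - 1][b - 1] > prev) prev = Y[a - 1][b - 1];
      M[a][b] = prev + s;
      double xo = (M[a - 1][b] > NEG / 2) ? M[a - 1][b] + sc.gap_open : NEG;
      double xe = (X[a - 1][b] > NEG / 2) ? X[a - 1][b] + sc.gap_extend : NEG;
      X[a][b] = std::max(xo, xe);
      double yo = (M[a][b - 1] > NEG / 2) ? M[a][b - 1] + sc.gap_open : NEG;
      double ye = (Y[a][b - 1] > NEG / 2) ? Y[a][b - 1] + sc.gap_extend : NEG;
      Y[a][b] = std::max(yo, ye);
      if (M[a][b] > best + 1e-12) { best = M[a][b]; ba = a; bb = b; }
    }
  }
  (void) dummy;
  if (traceback && ba > 0) {
    // Walk back through states; aligned pairs are emitted at M cells.
    int a = ba, b = bb, state = 0;  // 0=M, 1=X, 2=Y
    while (a > 0 && b > 0) {
      if (state == 0) {
        int type;
        int pos5 = mlen - (a - 1);
        double s = pair_score(r[a - 1], w[b - 1], sc, pos5, &type);
        out_mpos->push_back(pos5);
        out_wpos->push_back(b);
        out_type->push_back(type);
        double rest = M[a][b] - s;
        if (std::abs(rest) < 1e-9) break;  // alignment start
        if (std::abs(rest - M[a - 1][b - 1]) < 1e-9) state = 0;
        else if (std::abs(rest - X[a - 1][b - 1]) < 1e-9) state = 1;
        else state = 2;
        --a; --b;
      } else if (state == 1) {
        if (std::abs(X[a][b] - (M[a - 1][b] + sc.gap_open)) < 1e-9) state = 0;
        else state = 1;
        --a;
      } else {
        if (std::abs(Y[a][b] - (M[a][b - 1] + sc.gap_open)) < 1e-9) state = 0;
        else state = 2;
        --b;
      }
    }
    std::reverse(out_mpos->begin(), out_mpos->end());
    std::reverse(out_wpos->begin(), out_wpos->end());
    std::reverse(out_type->begin(), out_type->end());
  }
  return best;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// [[Rcpp::export]]
List duplex_align_cpp(std::string mirna, std::string window, double match,
                      double mismatch, double wobble, double gap_open,
                      double gap_extend, int seed_start, int seed_end,
                      double seed_scale) {
  DuplexScheme sc;
  sc.match = match; sc.mismatch = mismatch; sc.wobble = wobble;
  sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  sc.seed_scale = seed_scale; sc.seed_start = seed_start;
  sc.seed_end = seed_end;
  std::vector<int> r = encode(mirna);
  std::reverse(r.begin(), r.end());
  std::vector<int> w = encode(window);
  std::vector<int> mpos, wpos, type;
  double S = duplex_align_core(r, w, (int) mirna.size(), sc, true,
                               &mpos, &wpos, &type);
  return List::create(_["S"] = S, _["mirna_pos"] = wrap(mpos),
                      _["window_pos"] = wrap(wpos), _["type"] = wrap(type));
}

// Score every window of width `window_len` (stride 1) along a UTR.
// [[Rcpp::export]]
NumericVector duplex_scan_cpp(std::string mirna, std::string utr,
                              int window_len, double match, double mismatch,
                              double wobble, double gap_open,
                              double gap_extend, int seed_start, int seed_end,
                              double seed_scale) {
  DuplexScheme sc;
  sc.match = match; sc.mismatch = mismatch; sc.wobble = wobble;
  sc.gap_open = gap_open; sc.gap_extend = gap_extend;
  sc.seed_scale = seed_scale; sc.seed_start = seed_start;
  sc.seed_end = seed_end;
  std::vector<int> r = encode(mirna);
  std::reverse(r.begin(), r.end());
  std::vector<int> u = encode(utr);
  int n = (int) u.size();
  int nw = n - window_len + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int s0 = 0; s0 < nw; ++s0) {
    std::vector<int> w(u.begin() + s0, u.begin() + s0 + window_len);
    out[s0] = duplex_align_core(r, w, (int) mirna.size(), sc, false,
                                NULL, NULL, NULL);
  }
  return out;
}
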