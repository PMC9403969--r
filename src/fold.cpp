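// Reduced nearest-neighbor RNA folding engine.
//
// Zuker-style MFE recursion with traceback, a matching McCaskill partition
// function with outside (base-pair probability) pass, and a loop-decomposition
// evaluator for a given dot-bracket structure.  The energy model uses
// Watson-Crick + wobble stacking free energies, tabulated hairpin / bulge /
// internal loop initiation terms with Jacobson-Stockmayer extrapolation, a
// Ninio asymmetry penalty, a linear multibranch model and a terminal AU/GU
// helix-end penalty.  Parameters are free energies at 37 C, kcal/mol.
// Sequence-dependent refinements (terminal mismatches, dangles, special
// tetraloops, 1x1/2x2 tables) are deliberately omitted: z-scores compare a
// native window with composition-matched shuffles under the *same* model, so
// the reduced set preserves the contrast while keeping the engine dependency
// free.  Bases other than ACGU (ambiguity codes) never pair.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF_E = 1e9;
const int MAXLOOP = 30;          // max unpaired in bulge/internal loops
const int MIN_HAIRPIN = 3;       // min unpaired in a hairpin loop
const double ML_CLOSE = 3.4;     // multibranch closing penalty
const double ML_BRANCH = 0.4;    // per branch
const double ML_UNPAIRED = 0.0;  // per unpaired nucleotide
const double TERM_AU = 0.5;      // terminal AU/GU helix-end penalty
const double KT37 = 0.0019872 * 310.15; // kcal/mol at 37 C

// base codes: A=0 C=1 G=2 U=3, other=4
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4;
  }
}

// pair types 1..6: CG GC GU UG AU UA ; 0 = not pairable
inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

inline bool is_au_gu(int pt) { return pt >= 3; } // GU UG AU UA

// stack[p][q]: helix 5'-i(i+1)...(j-1)j-3' with pair p=(i,j) on pair q=(i+1,j-1)
const double STACK[7][7] = {
  //        -      CG     GC     GU     UG     AU     UA
  /* - */ { 0,     0,     0,     0,     0,     0,     0    },
  /* CG*/ { 0,   -3.30, -2.40, -2.10, -1.40, -2.10, -2.10 },
  /* GC*/ { 0,   -3.40, -3.30, -2.50, -1.50, -2.20, -2.40 },
  /* GU*/ { 0,   -2.50, -2.10, -1.40,  1.30, -1.40, -1.30 },
  /* UG*/ { 0,   -1.50, -1.40,  0.30, -0.50, -0.60, -1.00 },
  /* AU*/ { 0,   -2.10, -2.10, -1.40, -1.00, -0.90, -1.30 },
  /* UA*/ { 0,   -2.40, -2.10, -1.30, -0.60, -1.10, -1.40 },
};

const double HAIRPIN_INIT[31] = {
  INF_E, INF_E, INF_E,
  5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40, 6.50,
  6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10, 7.20, 7.20,
  7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50, 7.60, 7.60, 7.70
};

const double BULGE_INIT[31] = {
  INF_E,
  3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.57, 4.71, 4.84, 4.95,
  5.06, 5.15, 5.24, 5.32, 5.39, 5.46, 5.53, 5.59, 5.65, 5.70,
  5.76, 5.81, 5.85, 5.90, 5.94, 5.98, 6.02, 6.06, 6.10, 6.13
};

const double INTERNAL_INIT[31] = {
  INF_E, INF_E,
  1.70, 1.80, 1.10, 2.00, 1.90, 2.10, 2.30, 2.40, 2.50,
  2.60, 2.70, 2.78, 2.86, 2.94, 3.01, 3.07, 3.13, 3.19, 3.24,
  3.29, 3.34, 3.39, 3.43, 3.47, 3.51, 3.55, 3.59, 3.62, 3.66
};

const double NINIO_M = 0.6, NINIO_MAX = 3.0;

inline double loop_extrapolate(const double *tab, int n, int tabmax) {
  if (n <= tabmax) return tab[n];
  return tab[tabmax] + 1.75 * KT37 * std::log((double)n / tabmax);
}

struct EnergyModel {
  std::vector<int> s;   // base codes, 0-based
  std::vector<signed char> ptm; // cached pair types
  int n;

  explicit EnergyModel(const std::string &seq) {
    n = (int)seq.size();
    s.resize(n);
    for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);
    ptm.assign((size_t)n * n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        ptm[(size_t)i * n + j] = (signed char)pair_type(s[i], s[j]);
  }

  inline int pt(int i, int j) const { return ptm[(size_t)i * n + j]; }

  double hairpin(int i, int j) const { // pair (i,j) closing, 0-based
    int size = j - i - 1;
    if (size < MIN_HAIRPIN) return INF_E;
    double e = loop_extrapolate(HAIRPIN_INIT, size, 30);
    if (is_au_gu(pt(i, j))) e += TERM_AU;
    return e;
  }

  // two-pair loop: outer pair (i,j), inner pair (k,l), i<k<l<j
  double two_loop(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    int p1 = pt(i, j), p2 = pt(k, l);
    if (n1 == 0 && n2 == 0) return STACK[p1][p2];
    if (n1 + n2 > MAXLOOP) return INF_E;
    if (n1 == 0 || n2 == 0) { // bulge
      int size = n1 + n2;
      double e = loop_extrapolate(BULGE_INIT, size, 30);
      if (size == 1) {
        e += STACK[p1][p2]; // helix stacking continues across a 1-nt bulge
      } else {
        if (is_au_gu(p1)) e += TERM_AU;
        if (is_au_gu(p2)) e += TERM_AU;
      }
      return e;
    }
    int size = n1 + n2;
    double e = loop_extrapolate(INTERNAL_INIT, size, 30);
    e += std::min(NINIO_MAX, NINIO_M * std::abs(n1 - n2));
    if (is_au_gu(p1)) e += TERM_AU;
    if (is_au_gu(p2)) e += TERM_AU;
    return e;
  }

  inline double branch_penalty(int i, int j) const {
    return is_au_gu(pt(i, j)) ? TERM_AU : 0.0;
  }
};

inline int idx(int i, int j, int n) { return i * n + j; }

struct FoldArrays {
  int n;
  std::vector<double> V, WM;
  std::vector<double> W;
  FoldArrays(int n_) : n(n_), V(n_ * n_, INF_E), WM(n_ * n_, INF_E), W(n_ + 1, 0.0) {}
};

void fill_mfe(const EnergyModel &em, FoldArrays &fa) {
  int n = em.n;
  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j)
      double v = INF_E;
      if (em.pt(i, j)) {
        v = em.hairpin(i, j);
        int kmax = std::min(j - 1, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 1, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            if (!em.pt(k, l)) continue;
            double e = em.two_loop(i, j, k, l) + fa.V[idx(k, l, n)];
            if (e < v) v = e;
          }
        }
        // multibranch: >= 2 branches inside
        double close = ML_CLOSE + em.branch_penalty(i, j);
        for (int k = i + 1; k < j - 1; ++k) {
          double e = fa.WM[idx(i + 1, k, n)] + fa.WM[idx(k + 1, j - 1, n)] + close;
          if (e < v) v = e;
        }
      }
      fa.V[idx(i, j, n)] = v;
      // WM(i,j): >= 1 branch, multiloop interior weights
      double wm = INF_E;
      if (em.pt(i, j) && v < INF_E / 2)
        wm = v + ML_BRANCH + em.branch_penalty(i, j);
      if (fa.WM[idx(i + 1, j, n)] + ML_UNPAIRED < wm) wm = fa.WM[idx(i + 1, j, n)] + ML_UNPAIRED;
      if (fa.WM[idx(i, j - 1, n)] + ML_UNPAIRED < wm) wm = fa.WM[idx(i, j - 1, n)] + ML_UNPAIRED;
      for (int k = i + 1; k <= j - 1; ++k) {
        double e = fa.WM[idx(i, k - 1, n)] + fa.WM[idx(k, j, n)];
        if (e < wm) wm = e;
      }
      fa.WM[idx(i, j, n)] = wm;
    }
  }
  // exterior
  fa.W[0] = 0.0;
  for (int j = 0; j < n; ++j) {
    double w = (j > 0) ? fa.W[j] : 0.0; // W[j] == energy of prefix ending before j
    for (int i = 0; i <= j; ++i) {
      if (!em.pt(i, j)) continue;
      double e = (i > 0 ? fa.W[i] : 0.0) + fa.V[idx(i, j, n)] + em.branch_penalty(i, j);
      if (e < w) w = e;
    }
    fa.W[j + 1] = std::min(w, 0.0);
  }
}

// traceback helpers -------------------------------------------------------

void trace_V(const EnergyModel &em, const FoldArrays &fa, int i, int j,
             std::vector<int> &pair);
void trace_WM(const EnergyModel &em, const FoldArrays &fa, int i, int j,
              std::vector<int> &pair);

void trace_V(const EnergyModel &em, const FoldArrays &fa, int i, int j,
             std::vector<int> &pair) {
  int n = em.n;
  double v = fa.V[idx(i, j, n)];
  pair[i] = j; pair[j] = i;
  if (std::abs(v - em.hairpin(i, j)) < 1e-7) return;
  int kmax = std::min(j - 1, i + MAXLOOP + 1);
  for (int k = i + 1; k <= kmax; ++k) {
    int lmin = std::max(k + 1, j - 1 - (MAXLOOP - (k - i - 1)));
    for (int l = j - 1; l >= lmin; --l) {
      if (!em.pt(k, l)) continue;
      if (std::abs(v - (em.two_loop(i, j, k, l) + fa.V[idx(k, l, n)])) < 1e-7) {
        trace_V(em, fa, k, l, pair);
        return;
      }
    }
  }
  double close = ML_CLOSE + em.branch_penalty(i, j);
  for (int k = i + 1; k < j - 1; ++k) {
    if (std::abs(v - (fa.WM[idx(i + 1, k, n)] + fa.WM[idx(k + 1, j - 1, n)] + close)) < 1e-7) {
      trace_WM(em, fa, i + 1, k, pair);
      trace_WM(em, fa, k + 1, j - 1, pair);
      return;
    }
  }
  Rcpp::stop("traceback failure in V");
}

void trace_WM(const EnergyModel &em, const FoldArrays &fa, int i, int j,
              std::vector<int> &pair) {
  int n = em.n;
  double wm = fa.WM[idx(i, j, n)];
  if (em.pt(i, j) &&
      std::abs(wm - (fa.V[idx(i, j, n)] + ML_BRANCH + em.branch_penalty(i, j))) < 1e-7) {
    trace_V(em, fa, i, j, pair);
    return;
  }
  if (i + 1 <= j && std::abs(wm - (fa.WM[idx(i + 1, j, n)] + ML_UNPAIRED)) < 1e-7) {
    trace_WM(em, fa, i + 1, j, pair);
    return;
  }
  if (i <= j - 1 && std::abs(wm - (fa.WM[idx(i, j - 1, n)] + ML_UNPAIRED)) < 1e-7) {
    trace_WM(em, fa, i, j - 1, pair);
    return;
  }
  for (int k = i + 1; k <= j - 1; ++k) {
    if (std::abs(wm - (fa.WM[idx(i, k - 1, n)] + fa.WM[idx(k, j, n)])) < 1e-7) {
      trace_WM(em, fa, i, k - 1, pair);
      trace_WM(em, fa, k, j, pair);
      return;
    }
  }
  Rcpp::stop("traceback failure in WM");
}

void trace_W(const EnergyModel &em, const FoldArrays &fa, std::vector<int> &pair) {
  int n = em.n;
  int j = n - 1;
  while (j >= 0) {
    double w = fa.W[j + 1];
    if (std::abs(w - fa.W[j]) < 1e-9 && std::abs(w) < 1e-9) { --j; continue; }
    if (std::abs(w - fa.W[j]) < 1e-9) { --j; continue; }
    bool found = false;
    for (int i = 0; i <= j; ++i) {
      if (!em.pt(i, j)) continue;
      double e = (i > 0 ? fa.W[i] : 0.0) + fa.V[idx(i, j, n)] + em.branch_penalty(i, j);
      if (std::abs(w - e) < 1e-7) {
        trace_V(em, fa, i, j, pair);
        j = i - 1;
        found = true;
        break;
      }
    }
    if (!found) { --j; } // numerically flat case: treat as unpaired
  }
}

} // namespace

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  EnergyModel em(seq);
  int n = em.n;
  if (n == 0) stop("empty sequence");
  std::vector<int> pair(n, -1);
  double mfe = 0.0;
  if (n > MIN_HAIRPIN + 1) {
    FoldArrays fa(n);
    fill_mfe(em, fa);
    mfe = fa.W[n];
    if (mfe < -1e-9) trace_W(em, fa, pair);
    if (mfe > 0) mfe = 0.0;
  }
  std::string db(n, '.');
  IntegerVector pmate(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (pair[i] >= 0) {
      pmate[i] = pair[i] + 1;
      db[i] = (pair[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["structure"] = db, _["dg"] = mfe, _["pairs"] = pmate);
}

// Evaluate the free energy of a given dot-bracket structure by loop
// decomposition under the same model.
// [[Rcpp::export(name = ".energy_of_structure_cpp")]]
double energy_of_structure_cpp(std::string seq, std::string db) {
  EnergyModel em(seq);
  int n = em.n;
  if ((int)db.size() != n) stop("sequence/structure length mismatch");
  std::vector<int> pair(n, -1);
  std::vector<int> stk;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') stk.push_back(i);
    else if (db[i] == ')') {
      if (stk.empty()) stop("unbalanced dot-bracket");
      pair[i] = stk.back(); pair[stk.back()] = i; stk.pop_back();
    } else if (db[i] != '.') stop("invalid dot-bracket character");
  }
  if (!stk.empty()) stop("unbalanced dot-bracket");

  double total = 0.0;
  // recursively score loops closed by each pair; iterate outermost-in
  std::vector<std::pair<int,int> > closing;
  for (int i = 0; i < n; ++i) if (pair[i] > i) closing.push_back(std::make_pair(i, pair[i]));
  for (size_t c = 0; c < closing.size(); ++c) {
    int i = closing[c].first, j = closing[c].second;
    if (!em.pt(i, j)) stop("non-canonical pair in structure");
    // find branches immediately interior to (i,j)
    std::vector<std::pair<int,int> > br;
    int k = i + 1;
    int unpaired = 0;
    while (k < j) {
      if (pair[k] > k) { br.push_back(std::make_pair(k, pair[k])); k = pair[k] + 1; }
      else { ++unpaired; ++k; }
    }
    if (br.empty()) {
      total += em.hairpin(i, j);
    } else if (br.size() == 1) {
      double e = em.two_loop(i, j, br[0].first, br[0].second);
      if (e >= INF_E / 2) stop("loop exceeds model limits");
      total += e;
    } else {
      total += ML_CLOSE + em.branch_penalty(i, j) + ML_UNPAIRED * unpaired;
      for (size_t b = 0; b < br.size(); ++b)
        total += ML_BRANCH + em.branch_penalty(br[b].first, br[b].second);
    }
  }
  // exterior branches
  {
    int k = 0;
    while (k < n) {
      if (pair[k] > k) { total += em.branch_penalty(k, pair[k]); k = pair[k] + 1; }
      else ++k;
    }
  }
  return total;
}

// McCaskill partition function + outside pass; returns ensemble free energy,
// base-pair probability triplets and the ensemble diversity
// (mean base-pair distance, 2 * sum p(1-p)).
// [[Rcpp::export(name = ".partition_cpp")]]
List partition_cpp(std::string seq, double temperature_c) {
  EnergyModel em(seq);
  int n = em.n;
  if (n == 0) stop("empty sequence");
  double kT = 0.0019872 * (273.15 + temperature_c);

  std::vector<double> Qb(n * n, 0.0), Qm(n * n, 0.0), Qm1(n * n, 0.0);
  std::vector<double> Q(n + 1, 1.0), Qr(n + 2, 1.0); // prefix / suffix exterior

  double wb = std::exp(-ML_BRANCH / kT);
  double wc = std::exp(-ML_CLOSE / kT);
  double wu = std::exp(-ML_UNPAIRED / kT);

  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double qb = 0.0;
      if (em.pt(i, j)) {
        double eh = em.hairpin(i, j);
        if (eh < INF_E / 2) qb += std::exp(-eh / kT);
        int kmax = std::min(j - 1, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 1, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            if (!em.pt(k, l) || Qb[idx(k, l, n)] == 0.0) continue;
            double e = em.two_loop(i, j, k, l);
            if (e < INF_E / 2) qb += std::exp(-e / kT) * Qb[idx(k, l, n)];
          }
        }
        // multiloop
        double closew = wc * std::exp(-em.branch_penalty(i, j) / kT);
        double mlsum = 0.0;
        for (int k = i + 1; k < j - 1; ++k)
          mlsum += Qm[idx(i + 1, k, n)] * Qm1[idx(k + 1, j - 1, n)];
        qb += closew * mlsum;
      }
      Qb[idx(i, j, n)] = qb;
      // Qm1(i,j): one branch starting exactly at i, ending l<=j, rest unpaired
      double q1 = 0.0;
      for (int l = i + MIN_HAIRPIN + 1; l <= j; ++l) {
        double qb = Qb[idx(i, l, n)];
        if (qb == 0.0) continue;
        q1 += qb * wb * std::exp(-em.branch_penalty(i, l) / kT) *
              std::pow(wu, j - l);
      }
      Qm1[idx(i, j, n)] = q1;
      // Qm(i,j): >= 1 branch
      double qm = 0.0;
      for (int k = i; k <= j; ++k) {
        double q1k = Qm1[idx(k, j, n)];
        if (q1k == 0.0) continue;
        double left = std::pow(wu, k - i);
        if (k > i) left += Qm[idx(i, k - 1, n)];
        qm += left * q1k;
      }
      Qm[idx(i, j, n)] = qm;
    }
  }
  // exterior prefix Q[j+1] = partition of s[0..j]
  for (int j = 0; j < n; ++j) {
    double q = Q[j]; // j unpaired
    for (int i = 0; i <= j; ++i) {
      double qb = Qb[idx(i, j, n)];
      if (qb == 0.0) continue;
      q += (i > 0 ? Q[i] : 1.0) * qb * std::exp(-em.branch_penalty(i, j) / kT);
    }
    Q[j + 1] = q;
  }
  // exterior suffix Qr[i] = partition of s[i..n-1] (1-based offset: Qr[i], i 0..n)
  Qr[n] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double q = Qr[i + 1];
    for (int j = i; j < n; ++j) {
      double qb = Qb[idx(i, j, n)];
      if (qb == 0.0) continue;
      q += qb * std::exp(-em.branch_penalty(i, j) / kT) * Qr[j + 1];
    }
    Qr[i] = q;
  }
  double Qtot = Q[n];

  // outside: P[i,j]
  std::vector<double> P(n * n, 0.0);
  for (int span = n - 1; span > MIN_HAIRPIN; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double qb = Qb[idx(i, j, n)];
      if (qb == 0.0) continue;
      // exterior
      double p = (i > 0 ? Q[i] : 1.0) * qb *
                 std::exp(-em.branch_penalty(i, j) / kT) * Qr[j + 1] / Qtot;
      // enclosed by outer pair (k,l) as two-loop
      int kmin = std::max(0, i - MAXLOOP - 1);
      for (int k = kmin; k < i; ++k) {
        int lmax = std::min(n - 1, j + 1 + (MAXLOOP - (i - k - 1)));
        for (int l = j + 1; l <= lmax; ++l) {
          if (!em.pt(k, l)) continue;
          double pk = P[idx(k, l, n)];
          if (pk == 0.0 || Qb[idx(k, l, n)] == 0.0) continue;
          double e = em.two_loop(k, l, i, j);
          if (e < INF_E / 2)
            p += pk * std::exp(-e / kT) * qb / Qb[idx(k, l, n)];
        }
      }
      // enclosed in a multiloop closed by (k,l)
      double wbr = wb * std::exp(-em.branch_penalty(i, j) / kT);
      for (int k = 0; k < i; ++k) {
        for (int l = j + 1; l < n; ++l) {
          if (!em.pt(k, l)) continue;
          double pk = P[idx(k, l, n)];
          double qkl = Qb[idx(k, l, n)];
          if (pk == 0.0 || qkl == 0.0) continue;
          double closew = wc * std::exp(-em.branch_penalty(k, l) / kT);
          double left_empty = std::pow(wu, i - k - 1);
          double right_empty = std::pow(wu, l - j - 1);
          double left_qm = (i - 1 >= k + 1) ? Qm[idx(k + 1, i - 1, n)] : 0.0;
          double right_qm = (l - 1 >= j + 1) ? Qm[idx(j + 1, l - 1, n)] : 0.0;
          double combos = left_qm * right_empty + left_empty * right_qm +
                          left_qm * right_qm;
          if (combos == 0.0) continue;
          p += pk / qkl * closew * wbr * qb * combos;
        }
      }
      P[idx(i, j, n)] = p;
    }
  }

  double ed = 0.0;
  std::vector<int> pi, pj;
  std::vector<double> pv;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double p = P[idx(i, j, n)];
      if (p > 1.0 + 1e-6) p = 1.0; // guard tiny numeric overshoot
      if (p > 1e-8) { pi.push_back(i + 1); pj.push_back(j + 1); pv.push_back(p); }
      ed += 2.0 * p * (1.0 - p);
    }
  }
  double G = -kT * std::log(Qtot);
  return List::create(_["ensemble_dg"] = G, _["ed"] = ed,
                      _["i"] = wrap(pi), _["j"] = wrap(pj), _["p"] = wrap(pv));
}

// Fold many sequences, energies only (hot loop of the window scan).
// [[Rcpp::export(name = ".fold_energy_many_cpp")]]
NumericVector fold_energy_many_cpp(std::vector<std::string> seqs) {
  int m = (int)seqs.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    EnergyModel em(seqs[k]);
    int n = em.n;
    double mfe = 0.0;
    if (n > MIN_HAIRPIN + 1) {
      FoldArrays fa(n);
      fill_mfe(em, fa);
      mfe = std::min(fa.W[n], 0.0);
    }
    out[k] = mfe;
  }
  return out;
}
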