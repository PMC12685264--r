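// Minimum free energy of DNA secondary structure over non-crossing base
// pairs: Watson-Crick pairs (G.T wobble optional), nearest-neighbor
// stacking, tabulated hairpin/bulge/internal loop penalties with
// logarithmic extrapolation. Multiloops are excluded (nested stems and
// simple loops only), which keeps the recursion at O(L^2 * max_loop^2);
// the profile statistics downstream need relative window-to-window
// stability, not publication-grade MFE.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct FoldParams {
  std::vector<double> stack;   // 4x4 row-major [first*4 + second]
  std::vector<double> hairpin, bulge, internal_;
  double lxc, asym, asym_max, wobble_stack;
  int min_hairpin, max_loop;
  bool wobble;
};

static inline bool pairable(int a, int b, bool wobble) {
  if (a < 0 || b < 0) return false;
  if (a + b == 3) return true;                 // A.T (0,3) and C.G (1,2)
  if (wobble && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true;
  return false;
}

static inline bool is_wc(int a, int b) { return a + b == 3; }

static inline double loop_tab(const std::vector<double>& tab, int n,
                              double lxc) {
  if (n <= 0) return INF;
  if (n <= (int)tab.size()) return tab[n - 1];
  return tab.back() + lxc * std::log((double)n / (double)tab.size());
}

static inline double hairpin_e(const FoldParams& p, int n) {
  if (n < p.min_hairpin) return INF;
  return loop_tab(p.hairpin, n, p.lxc);
}

static inline double interior_e(const FoldParams& p, int n1, int n2) {
  if (n1 == 0 && n2 == 0) return INF;  // that is a stack, handled apart
  if (n1 == 0 || n2 == 0) return loop_tab(p.bulge, n1 + n2, p.lxc);
  double asym = p.asym * std::abs(n1 - n2);
  if (asym > p.asym_max) asym = p.asym_max;
  return loop_tab(p.internal_, n1 + n2, p.lxc) + asym;
}

static inline double stack_e(const FoldParams& p, int si, int si1,
                             int sj, int sj1) {
  if (is_wc(si, sj) && is_wc(si1, sj1))
    return p.stack[si * 4 + si1];
  return p.wobble_stack;  // any step touching a wobble pair: flat value
}

// [[Rcpp::export(name = ".fold_dna_cpp")]]
double fold_dna_cpp(std::string seq, NumericMatrix stack,
                    NumericVector hairpin, NumericVector bulge,
                    NumericVector internal_, double lxc, double asym,
                    double asym_max, double wobble_stack,
                    int min_hairpin, int max_loop, bool wobble) {
  const int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = enc(seq[i]);
    if (s[i] < 0) stop("fold: sequence alphabet must be ACGT");
  }
  FoldParams p;
  p.stack.assign(16, 0.0);
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) p.stack[a * 4 + b] = stack(a, b);
  p.hairpin = as<std::vector<double> >(hairpin);
  p.bulge = as<std::vector<double> >(bulge);
  p.internal_ = as<std::vector<double> >(internal_);
  p.lxc = lxc; p.asym = asym; p.asym_max = asym_max;
  p.wobble_stack = wobble_stack;
  p.min_hairpin = min_hairpin; p.max_loop = max_loop; p.wobble = wobble;

  // V[i][j]: MFE of a structure closed by pair (i, j); INF if unpairable
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  for (int j = min_hairpin + 1; j < n; ++j) {
    for (int i = j - min_hairpin - 1; i >= 0; --i) {
      if (!pairable(s[i], s[j], wobble)) continue;
      double e = hairpin_e(p, j - i - 1);
      if (i + 1 < j - 1 && V[i + 1][j - 1] < INF)
        e = std::min(e, stack_e(p, s[i], s[i + 1], s[j], s[j - 1]) +
                        V[i + 1][j - 1]);
      int kmax = std::min(i + 1 + max_loop, j - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int n1 = k - i - 1;
        int lmin = std::max(k + 1, j - 1 - (max_loop - n1));
        for (int l = j - 1; l >= lmin; --l) {
          int n2 = j - l - 1;
          if (n1 == 0 && n2 == 0) continue;
          if (V[k][l] < INF)
            e = std::min(e, interior_e(p, n1, n2) + V[k][l]);
        }
      }
      V[i][j] = e;
    }
  }

  // W[j]: MFE of the prefix of length j (top level may hold several stems)
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    for (int i = 0; i + min_hairpin + 1 < j; ++i)
      if (V[i][j - 1] < INF)
        W[j] = std::min(W[j], W[i] + V[i][j - 1]);
  }
  return std::min(W[n], 0.0);
}
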