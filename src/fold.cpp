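#include <Rcpp.h>
#include <cctype>
#include <string>
#include <vector>
using namespace Rcpp;

// Coarse RNA base-pair stabilities (kcal/mol): Watson-Crick G:C strongest,
// A:U intermediate, G:U wobble weakest. Positive return = pairing disallowed.
static inline double pair_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0;
}

// Weighted Nussinov minimisation: E(i,j) = min( E(i,j-1),
//   min_k E(i,k-1) + e(k,j) + E(k+1,j-1) ) with a minimum hairpin loop of 3
// unpaired bases (k <= j-4). The open chain scores 0, so the minimum free
// energy is always <= 0 and an unpairable homopolymer folds to exactly 0.
static double mfe_one(const std::string &s) {
  const int n = (int)s.size();
  if (n < 5) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len <= n; ++i) {
      const int j = i + len - 1;
      double best = E[(size_t)i * n + j - 1];
      for (int k = i; k <= j - 4; ++k) {
        const double pe = pair_e(s[k], s[j]);
        if (pe < 0.0) {
          double v = pe + E[(size_t)(k + 1) * n + j - 1];
          if (k > i) v += E[(size_t)i * n + k - 1];
          if (v < best) best = v;
        }
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return E[(size_t)(n - 1)];
}

static std::string to_rna(std::string s) {
  for (auto &c : s) {
    c = (char)std::toupper((unsigned char)c);
    if (c == 'T') c = 'U';
  }
  return s;
}

// [[Rcpp::export(name = ".mfe_nussinov")]]
double mfe_nussinov(std::string seq) { return mfe_one(to_rna(seq)); }

// [[Rcpp::export(name = ".fold_windows_nussinov")]]
NumericVector fold_windows_nussinov(std::string seq, int window, int step) {
  const std::string s = to_rna(seq);
  const int n = (int)s.size();
  if (window < 1 || step < 1) stop("window and step must be >= 1");
  if (n < window) return NumericVector(0);
  const int m = (n - window) / step + 1;
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = mfe_one(s.substr((size_t)i * step, (size_t)window));
  return out;
}
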