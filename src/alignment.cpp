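#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs.
//
// Returns the optimal alignment score and, among all score-optimal
// alignments, the maximum number of aligned columns whose characters are
// identical.  The second quantity is well defined because any score-optimal
// path decomposes into score-optimal prefixes, so a second DP restricted to
// edges lying on optimal paths is exact.
//
// Characters compare by strict equality: IUPAC ambiguity codes never match
// anything but themselves.
// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string a, std::string b,
             double match, double mismatch, double gap) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");

  const double NEG = -1e18;
  // rolling rows: S = best score, M = max matches among best-score paths
  std::vector<double> Sprev(m + 1), Scur(m + 1);
  std::vector<int> Mprev(m + 1), Mcur(m + 1);

  Sprev[0] = 0.0; Mprev[0] = 0;
  for (int j = 1; j <= m; ++j) { Sprev[j] = j * gap; Mprev[j] = 0; }

  for (int i = 1; i <= n; ++i) {
    Scur[0] = i * gap; Mcur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool eq = (ai == b[j - 1]);
      const double sDiag = Sprev[j - 1] + (eq ? match : mismatch);
      const double sUp   = Sprev[j] + gap;
      const double sLeft = Scur[j - 1] + gap;
      double best = sDiag;
      if (sUp > best) best = sUp;
      if (sLeft > best) best = sLeft;
      int mm = (int)NEG;
      if (sDiag == best) {
        int cand = Mprev[j - 1] + (eq ? 1 : 0);
        if (cand > mm) mm = cand;
      }
      if (sUp == best && Mprev[j] > mm) mm = Mprev[j];
      if (sLeft == best && Mcur[j - 1] > mm) mm = Mcur[j - 1];
      Scur[j] = best; Mcur[j] = mm;
    }
    std::swap(Sprev, Scur);
    std::swap(Mprev, Mcur);
  }

  return List::create(_["score"] = Sprev[m], _["matches"] = Mprev[m]);
}
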