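#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Max cluster mass for one t-map laid out as nCh x nT (column j of the
// flattened map = point index j = t*nCh + c). Cluster members share the sign
// of t and are connected via temporal succession on a channel or spatial
// adjacency at a time sample. Non-finite t-scores are capped at the largest
// finite magnitude in the map.
static double maxClusterMass(std::vector<double> &t, int nCh, int nT,
                             double tCrit, bool twoSided, int signDir,
                             const std::vector<std::vector<int> > &adj,
                             std::vector<int> &lab, std::vector<int> &stack) {
  double cap = 0.0;
  bool hasInf = false;
  for (size_t i = 0; i < t.size(); ++i) {
    if (std::isfinite(t[i])) {
      double a = std::fabs(t[i]);
      if (a > cap) cap = a;
    } else hasInf = true;
  }
  if (hasInf) {
    if (cap == 0.0) cap = 1.0;
    for (size_t i = 0; i < t.size(); ++i)
      if (!std::isfinite(t[i])) t[i] = (t[i] > 0 ? cap : -cap);
  }
  std::fill(lab.begin(), lab.end(), 0);
  int cid = 0;
  double best = 0.0;
  const int nPts = nCh * nT;
  for (int p0 = 0; p0 < nPts; ++p0) {
    double v = t[p0];
    bool supra = twoSided ? (std::fabs(v) >= tCrit) : (signDir * v >= tCrit);
    if (!supra || lab[p0]) continue;
    ++cid;
    int sgn = v > 0 ? 1 : -1;
    double mass = 0.0;
    stack.clear();
    stack.push_back(p0);
    lab[p0] = cid;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      mass += t[p];
      int c = p % nCh, tt = p / nCh;
      // candidate neighbours
      for (int k = -1; k <= 1; k += 2) {  // temporal
        int t2 = tt + k;
        if (t2 < 0 || t2 >= nT) continue;
        int q = t2 * nCh + c;
        double w = t[q];
        bool s2 = twoSided ? (std::fabs(w) >= tCrit) : (signDir * w >= tCrit);
        if (s2 && !lab[q] && ((w > 0 ? 1 : -1) == sgn)) {
          lab[q] = cid;
          stack.push_back(q);
        }
      }
      for (size_t a = 0; a < adj[c].size(); ++a) {  // spatial
        int q = tt * nCh + adj[c][a];
        double w = t[q];
        bool s2 = twoSided ? (std::fabs(w) >= tCrit) : (signDir * w >= tCrit);
        if (s2 && !lab[q] && ((w > 0 ? 1 : -1) == sgn)) {
          lab[q] = cid;
          stack.push_back(q);
        }
      }
    }
    double stat = twoSided ? std::fabs(mass) : signDir * mass;
    if (stat > best) best = stat;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector permNullMaxMass(const NumericMatrix &D,
                              const NumericMatrix &signs, double tCrit,
                              const List &adjIdx, int nCh, int nT,
                              bool twoSided, int signDir) {
  const int n = D.nrow();
  const int nPts = D.ncol();
  if (nPts != nCh * nT) stop("D has %d columns, expected %d", nPts, nCh * nT);
  if (signs.ncol() != n) stop("signs must have one column per participant");

  std::vector<std::vector<int> > adj(nCh);
  for (int c = 0; c < nCh; ++c) {
    IntegerVector v = adjIdx[c];
    adj[c] = std::vector<int>(v.begin(), v.end());
    for (size_t k = 0; k < adj[c].size(); ++k)
      if (adj[c][k] < 0 || adj[c][k] >= nCh) stop("adjacency index out of range");
  }
  // sum of squares per point is invariant under sign flips
  std::vector<double> sumsq(nPts, 0.0);
  for (int j = 0; j < nPts; ++j) {
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += D(i, j) * D(i, j);
    sumsq[j] = ss;
  }
  const int nPerm = signs.nrow();
  NumericVector out(nPerm);
  std::vector<double> t(nPts);
  std::vector<int> lab(nPts), stack;
  stack.reserve(nPts);
  const double dn = (double)n;
  for (int p = 0; p < nPerm; ++p) {
    for (int j = 0; j < nPts; ++j) {
      double sum = 0.0;
      for (int i = 0; i < n; ++i) sum += signs(p, i) * D(i, j);
      double m = sum / dn;
      double var = (sumsq[j] - dn * m * m) / (dn - 1.0);
      if (var <= 0.0) {
        t[j] = (m == 0.0) ? 0.0
                          : (m > 0 ? R_PosInf : R_NegInf);
      } else {
        t[j] = m / std::sqrt(var / dn);
      }
    }
    out[p] = maxClusterMass(t, nCh, nT, tCrit, twoSided, signDir, adj, lab,
                            stack);
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
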