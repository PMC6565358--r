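#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <string>
using namespace Rcpp;

// Atomize-and-agglomerate hierarchical clustering of scalp maps.
// X: channels x samples, average-referenced. Each sample starts as its own
// cluster; the cluster contributing least to the global explained variance is
// atomized and its members reassigned to the cluster whose (unit-norm)
// centroid has the highest squared spatial correlation, until kMin clusters
// remain. Centroids are polarity-aligned normalized member means.
//
// While many clusters remain, "contributing least" is measured by the
// cluster's own explained sum of squares (cheap, and harmless while clusters
// are small). Below a refinement bound the exact criterion is used: the loss
// in explained variance if the cluster were atomized and its members moved to
// their next-best centroids. This protects coherent low-field-power maps from
// being absorbed while duplicate clusters of the same map still exist.

struct Cluster {
  std::vector<int> members;
  std::vector<double> centroid;
  double contrib;
  bool alive;
};

static void recomputeCentroid(const NumericMatrix &X, Cluster &cl) {
  const int C = X.nrow();
  cl.centroid.assign(C, 0.0);
  const int ref = cl.members.front();
  for (size_t m = 0; m < cl.members.size(); ++m) {
    int n = cl.members[m];
    double d = 0.0;
    for (int c = 0; c < C; ++c) d += X(c, n) * X(c, ref);
    double s = (d < 0.0) ? -1.0 : 1.0;  // align polarity to first member
    for (int c = 0; c < C; ++c) cl.centroid[c] += s * X(c, n);
  }
  double nrm = 0.0;
  for (int c = 0; c < C; ++c) nrm += cl.centroid[c] * cl.centroid[c];
  nrm = std::sqrt(nrm);
  if (nrm > 0) for (int c = 0; c < C; ++c) cl.centroid[c] /= nrm;
  cl.contrib = 0.0;
  for (size_t m = 0; m < cl.members.size(); ++m) {
    int n = cl.members[m];
    double d = 0.0;
    for (int c = 0; c < C; ++c) d += X(c, n) * cl.centroid[c];
    cl.contrib += d * d;
  }
}

static double clusterDot(const NumericMatrix &X, const Cluster &cl, int n) {
  double d = 0.0;
  for (int c = 0; c < X.nrow(); ++c) d += X(c, n) * cl.centroid[c];
  return d;
}

// [[Rcpp::export]]
List aahcCpp(const NumericMatrix &X, const IntegerVector &kRecord,
             int refineBound = 0) {
  const int C = X.nrow();
  const int N = X.ncol();
  if (N < 1) stop("no samples");
  int kMin = N, kMax = 1;
  for (int i = 0; i < kRecord.size(); ++i) {
    if (kRecord[i] < 1 || kRecord[i] > N) stop("requested K out of 1..N");
    if (kRecord[i] < kMin) kMin = kRecord[i];
    if (kRecord[i] > kMax) kMax = kRecord[i];
  }
  if (refineBound <= 0) refineBound = std::max(64, 4 * kMax);

  std::vector<double> norms2(N, 0.0);
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    double s = 0.0;
    for (int c = 0; c < C; ++c) s += X(c, n) * X(c, n);
    norms2[n] = s;
    total += s;
  }
  if (total <= 0) stop("input has zero variance");

  std::vector<Cluster> clusters(N);
  std::vector<int> assign(N);
  for (int n = 0; n < N; ++n) {
    clusters[n].members.assign(1, n);
    clusters[n].centroid.assign(C, 0.0);
    double nrm = std::sqrt(norms2[n]);
    if (nrm > 0)
      for (int c = 0; c < C; ++c) clusters[n].centroid[c] = X(c, n) / nrm;
    clusters[n].contrib = norms2[n];
    clusters[n].alive = true;
    assign[n] = n;
  }
  int alive = N;

  List out;
  std::vector<int> wantK(kRecord.begin(), kRecord.end());
  auto snapshot = [&](int K) {
    std::vector<int> ids;
    for (int q = 0; q < (int)clusters.size(); ++q)
      if (clusters[q].alive) ids.push_back(q);
    IntegerVector labels(N);
    NumericMatrix templates(C, K);
    double expl = 0.0;
    for (int k = 0; k < K; ++k) {
      const Cluster &cl = clusters[ids[k]];
      for (int c = 0; c < C; ++c) templates(c, k) = cl.centroid[c];
      for (size_t m = 0; m < cl.members.size(); ++m)
        labels[cl.members[m]] = k + 1;
      expl += cl.contrib;
    }
    out[std::to_string(K)] = List::create(
        _["labels"] = labels, _["templates"] = templates,
        _["explainedVariance"] = expl / total,
        _["sigma2"] = (total - expl) / ((double)N * (C - 1)));
  };

  auto atomize = [&](int worst) {
    std::vector<int> freed;
    freed.swap(clusters[worst].members);
    clusters[worst].alive = false;
    --alive;
    std::vector<int> dirty;
    for (size_t m = 0; m < freed.size(); ++m) {
      int n = freed[m];
      int best = -1;
      double bval = -1.0;
      for (int q = 0; q < (int)clusters.size(); ++q) {
        if (!clusters[q].alive) continue;
        double d = clusterDot(X, clusters[q], n);
        if (d * d > bval) {
          bval = d * d;
          best = q;
        }
      }
      clusters[best].members.push_back(n);
      assign[n] = best;
      bool seen = false;
      for (size_t j = 0; j < dirty.size(); ++j)
        if (dirty[j] == best) { seen = true; break; }
      if (!seen) dirty.push_back(best);
    }
    for (size_t j = 0; j < dirty.size(); ++j)
      recomputeCentroid(X, clusters[dirty[j]]);
  };

  for (size_t i = 0; i < wantK.size(); ++i)
    if (wantK[i] == alive) snapshot(alive);

  // phase 1: cheap contribution criterion
  while (alive > kMin && alive > refineBound) {
    int worst = -1;
    double wval = std::numeric_limits<double>::infinity();
    for (int q = 0; q < (int)clusters.size(); ++q)
      if (clusters[q].alive && clusters[q].contrib < wval) {
        wval = clusters[q].contrib;
        worst = q;
      }
    atomize(worst);
    for (size_t i = 0; i < wantK.size(); ++i)
      if (wantK[i] == alive) snapshot(alive);
    if (alive % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // phase 2: exact explained-variance loss criterion
  while (alive > kMin) {
    std::vector<int> ids;
    for (int q = 0; q < (int)clusters.size(); ++q)
      if (clusters[q].alive) ids.push_back(q);
    const int K = (int)ids.size();
    // cached squared dots of every sample with every live centroid
    std::vector<double> D2((size_t)N * K);
    for (int k = 0; k < K; ++k)
      for (int n = 0; n < N; ++n) {
        double d = clusterDot(X, clusters[ids[k]], n);
        D2[(size_t)n * K + k] = d * d;
      }
    std::vector<double> loss(K, 0.0);
    std::vector<int> pos(clusters.size(), -1);
    for (int k = 0; k < K; ++k) pos[ids[k]] = k;
    for (int n = 0; n < N; ++n) {
      int own = pos[assign[n]];
      double bestOther = 0.0;
      for (int k = 0; k < K; ++k) {
        if (k == own) continue;
        double v = D2[(size_t)n * K + k];
        if (v > bestOther) bestOther = v;
      }
      loss[own] += D2[(size_t)n * K + own] - bestOther;
    }
    int worst = ids[0];
    double wval = std::numeric_limits<double>::infinity();
    for (int k = 0; k < K; ++k)
      if (loss[k] < wval) {
        wval = loss[k];
        worst = ids[k];
      }
    atomize(worst);
    for (size_t i = 0; i < wantK.size(); ++i)
      if (wantK[i] == alive) snapshot(alive);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
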