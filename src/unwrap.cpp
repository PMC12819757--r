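#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided 3-D phase unwrapping by region growing.
//
// Voxels inside the mask are visited in descending quality order among the
// frontier of the already-unwrapped region (6-connectivity). Each newly
// visited voxel's phase is shifted by the integer multiple of 2*pi that
// brings it closest to the mean unwrapped phase of its visited 6-neighbours.
// Disconnected mask components are unwrapped independently; each component's
// seed is the caller-supplied seed voxel (first component only) or its
// highest-quality voxel, ties broken by lexicographic (linear) index.
//
// wrapped, quality: full-volume doubles; mask: full-volume 0/1 ints;
// dims: 3 ints; seed0: 0-based linear index or -1.
// Returns list(phase = unwrapped doubles, component = int component id
// per voxel, 0 outside mask).
// [[Rcpp::export(name = ".unwrap_region_grow")]]
List unwrap_region_grow(NumericVector wrapped, IntegerVector mask,
                        IntegerVector dims, NumericVector quality,
                        int seed0) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double TWO_PI = 2.0 * M_PI;
  NumericVector out(n);
  IntegerVector comp(n);
  std::vector<char> visited(n, 0);

  // priority queue entries: (quality, -index) so equal-quality ties pop the
  // smaller linear index first
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<std::vector<QE>::value_type> pq;

  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;

  auto push_neighbours = [&](R_xlen_t v) {
    int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / s3);
    const R_xlen_t nb[6] = {v - s1, v + s1, v - s2, v + s2, v - s3, v + s3};
    const bool ok[6] = {i > 0, i < n1 - 1, j > 0, j < n2 - 1, k > 0, k < n3 - 1};
    for (int t = 0; t < 6; ++t)
      if (ok[t] && mask[nb[t]] && !visited[nb[t]])
        pq.push(QE(quality[nb[t]], -nb[t]));
  };

  int current_comp = 0;
  bool first_component = true;

  for (R_xlen_t scan = 0; scan < n; ++scan) {
    if (!mask[scan] || visited[scan]) continue;
    // pick the seed of this connected component
    R_xlen_t seed = -1;
    if (first_component && seed0 >= 0 && mask[seed0] && !visited[seed0]) {
      seed = seed0;
    } else {
      // highest quality unvisited voxel reachable from `scan`: flood the
      // component first (cheap BFS) to restrict the argmax to it
      std::vector<R_xlen_t> stack;
      std::vector<R_xlen_t> members;
      stack.push_back(scan);
      std::vector<char> instack(0);
      // temporary mark with comp = -1 to avoid revisiting during BFS
      comp[scan] = -1;
      while (!stack.empty()) {
        R_xlen_t v = stack.back(); stack.pop_back();
        members.push_back(v);
        int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / s3);
        const R_xlen_t nb[6] = {v - s1, v + s1, v - s2, v + s2, v - s3, v + s3};
        const bool ok[6] = {i > 0, i < n1 - 1, j > 0, j < n2 - 1,
                            k > 0, k < n3 - 1};
        for (int t = 0; t < 6; ++t)
          if (ok[t] && mask[nb[t]] && !visited[nb[t]] && comp[nb[t]] != -1) {
            comp[nb[t]] = -1;
            stack.push_back(nb[t]);
          }
      }
      double bestq = R_NegInf;
      for (R_xlen_t v : members) {
        if (quality[v] > bestq || (quality[v] == bestq && v < seed)) {
          bestq = quality[v];
          seed = v;
        }
      }
      for (R_xlen_t v : members) comp[v] = 0;  // restore
    }
    first_component = false;
    ++current_comp;

    visited[seed] = 1;
    out[seed] = wrapped[seed];
    comp[seed] = current_comp;
    push_neighbours(seed);

    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      R_xlen_t v = -top.second;
      if (visited[v]) continue;
      // mean unwrapped phase of visited 6-neighbours
      int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / s3);
      const R_xlen_t nb[6] = {v - s1, v + s1, v - s2, v + s2, v - s3, v + s3};
      const bool ok[6] = {i > 0, i < n1 - 1, j > 0, j < n2 - 1,
                          k > 0, k < n3 - 1};
      double acc = 0.0; int cnt = 0;
      for (int t = 0; t < 6; ++t)
        if (ok[t] && visited[nb[t]] && mask[nb[t]]) { acc += out[nb[t]]; ++cnt; }
      if (cnt == 0) continue;  // stale frontier entry from a previous component
      const double ref = acc / cnt;
      out[v] = wrapped[v] + TWO_PI * std::round((ref - wrapped[v]) / TWO_PI);
      visited[v] = 1;
      comp[v] = current_comp;
      push_neighbours(v);
    }
  }
  return List::create(_["phase"] = out, _["component"] = comp);
}

// 6-connected component labelling of a binary volume. Returns integer labels
// (0 outside), components numbered from 1 in scan order.
// [[Rcpp::export(name = ".label_components_6")]]
IntegerVector label_components_6(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++cur;
    lab[start] = cur;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % n1), j = (int)((v / n1) % n2), k = (int)(v / s3);
      const R_xlen_t nb[6] = {v - s1, v + s1, v - s2, v + s2, v - s3, v + s3};
      const bool ok[6] = {i > 0, i < n1 - 1, j > 0, j < n2 - 1,
                          k > 0, k < n3 - 1};
      for (int t = 0; t < 6; ++t)
        if (ok[t] && mask[nb[t]] && !lab[nb[t]]) {
          lab[nb[t]] = cur;
          stack.push_back(nb[t]);
        }
    }
  }
  return lab;
}
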