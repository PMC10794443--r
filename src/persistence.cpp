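// Vietoris-Rips persistence for a symmetric dissimilarity matrix,
// dimensions 0 and 1 only (simplices up to triangles).
//
// H0: Kruskal sweep with union-find; the finite deaths are the
// minimum-spanning-tree edge weights (elder rule).
// H1: standard boundary-matrix reduction of the triangle/edge incidence
// over GF(2), columns processed in filtration order. Edges not in the MST
// create 1-cycles; a reduced triangle column whose lowest edge is such a
// creator pairs with it. Zero-persistence dim-1 pairs are dropped.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

struct Edge {
  double w;
  int i, j;
};
struct Tri {
  double w;
  int e1, e2, e3;  // indices into the sorted edge list, descending
};

// [[Rcpp::export(name = ".vr_persistence_cpp")]]
List vr_persistence_cpp(NumericMatrix D, double epsMax) {
  int n = D.nrow();
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = D(i, j);
      if (w <= epsMax) edges.push_back({w, i, j});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.w < b.w; });
  int m = (int)edges.size();

  // H0 sweep; also flag which edges create cycles (dim-1 creators)
  UnionFind uf(n);
  std::vector<double> h0Death;
  std::vector<char> creator(m, 0);
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j))
      h0Death.push_back(edges[e].w);
    else
      creator[e] = 1;
  }
  int h0Inf = n - (int)h0Death.size();  // components alive at epsMax

  // edge index lookup (i < j) -> position in sorted order
  std::vector<int> eidx((size_t)n * n, -1);
  for (int e = 0; e < m; ++e)
    eidx[(size_t)edges[e].i * n + edges[e].j] = e;

  // triangles entering the filtration at their largest edge weight
  std::vector<Tri> tris;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      int eab = eidx[(size_t)a * n + b];
      if (eab < 0) continue;
      for (int c = b + 1; c < n; ++c) {
        int eac = eidx[(size_t)a * n + c];
        int ebc = eidx[(size_t)b * n + c];
        if (eac < 0 || ebc < 0) continue;
        int lo = eab, mid = eac, hi = ebc;
        if (lo > mid) std::swap(lo, mid);
        if (mid > hi) std::swap(mid, hi);
        if (lo > mid) std::swap(lo, mid);
        tris.push_back({edges[hi].w, hi, mid, lo});
      }
    }
  std::stable_sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
    if (a.w != b.w) return a.w < b.w;
    return a.e1 < b.e1;
  });

  // reduction: lowOwner[e] = stored reduced column with low e
  std::vector<std::vector<int>> cols;  // descending edge indices
  std::vector<int> lowOwner(m, -1);
  std::vector<double> h1Birth, h1Death;
  std::vector<char> paired(m, 0);
  std::vector<int> work, tmp;
  for (size_t tIdx = 0; tIdx < tris.size(); ++tIdx) {
    const Tri& tr = tris[tIdx];
    work.assign({tr.e1, tr.e2, tr.e3});
    while (!work.empty()) {
      int low = work[0];
      int owner = lowOwner[low];
      if (owner < 0) break;
      // symmetric difference of two descending sorted lists
      const std::vector<int>& other = cols[owner];
      tmp.clear();
      size_t p = 0, q = 0;
      while (p < work.size() && q < other.size()) {
        if (work[p] == other[q]) {
          ++p;
          ++q;
        } else if (work[p] > other[q]) {
          tmp.push_back(work[p++]);
        } else {
          tmp.push_back(other[q++]);
        }
      }
      while (p < work.size()) tmp.push_back(work[p++]);
      while (q < other.size()) tmp.push_back(other[q++]);
      work.swap(tmp);
    }
    if (!work.empty()) {
      int low = work[0];
      cols.push_back(work);
      lowOwner[low] = (int)cols.size() - 1;
      paired[low] = 1;
      double b = edges[low].w, d = tr.w;
      if (d > b) {  // zero-persistence pairs carry no topology
        h1Birth.push_back(b);
        h1Death.push_back(d);
      }
    }
  }
  // creators never killed: essential 1-cycles at epsMax
  for (int e = 0; e < m; ++e)
    if (creator[e] && !paired[e]) {
      h1Birth.push_back(edges[e].w);
      h1Death.push_back(R_PosInf);
    }

  std::sort(h0Death.begin(), h0Death.end());
  return List::create(_["h0Death"] = wrap(h0Death), _["h0Inf"] = h0Inf,
                      _["h1Birth"] = wrap(h1Birth),
                      _["h1Death"] = wrap(h1Death));
}
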