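#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <limits>
using namespace Rcpp;

// Yen's loopless k-shortest-paths on a directed graph with positive edge
// costs. Nodes are 0-based internally, 1-based at the R boundary.
// Determinism for equal-cost alternatives: Dijkstra prefers the smaller
// predecessor index at exact distance ties, and the returned list is sorted
// by (cost, lexicographic node sequence).

namespace {

struct Graph {
  int n;
  std::vector<int> head;            // CSR offsets, size n+1
  std::vector<int> to;              // edge targets
  std::vector<double> w;            // edge costs
};

const double INF = std::numeric_limits<double>::infinity();

// Dijkstra from src to dst honouring removed edge/node masks.
// Returns path (src..dst) and its cost, or empty path if unreachable.
bool dijkstra(const Graph &g, int src, int dst,
              const std::vector<char> &edge_off,
              const std::vector<char> &node_off,
              std::vector<int> &path, double &cost) {
  std::vector<double> dist(g.n, INF);
  std::vector<int> pred(g.n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  dist[src] = 0.0;
  q.push(QE(0.0, src));
  while (!q.empty()) {
    QE top = q.top(); q.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    if (u == dst) break;
    for (int e = g.head[u]; e < g.head[u + 1]; ++e) {
      if (edge_off[e]) continue;
      int v = g.to[e];
      if (node_off[v]) continue;
      double nd = dist[u] + g.w[e];
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        q.push(QE(nd, v));
      } else if (nd == dist[v] && pred[v] >= 0 && u < pred[v]) {
        pred[v] = u;
      }
    }
  }
  if (dist[dst] == INF) return false;
  cost = dist[dst];
  path.clear();
  for (int v = dst; v != -1; v = pred[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return true;
}

bool lex_less(const std::vector<int> &a, const std::vector<int> &b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

struct Candidate {
  double cost;
  std::vector<int> path;
  bool operator<(const Candidate &o) const {
    if (cost != o.cost) return cost < o.cost;
    return lex_less(path, o.path);
  }
};

}  // namespace

// [[Rcpp::export(name = ".yen_cpp")]]
List yen_cpp(int n, IntegerVector from, IntegerVector to, NumericVector w,
             int src, int dst, int k) {
  const int m = from.size();
  // build CSR sorted by (from, to) so edge iteration order is canonical
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (from[a] != from[b]) return from[a] < from[b];
    return to[a] < to[b];
  });
  Graph g;
  g.n = n;
  g.head.assign(n + 1, 0);
  g.to.resize(m);
  g.w.resize(m);
  for (int i = 0; i < m; ++i) g.head[from[order[i]] - 1 + 1]++;
  for (int i = 0; i < n; ++i) g.head[i + 1] += g.head[i];
  {
    std::vector<int> pos(g.head.begin(), g.head.end() - 1);
    for (int i = 0; i < m; ++i) {
      int e = order[i];
      int p = pos[from[e] - 1]++;
      g.to[p] = to[e] - 1;
      g.w[p] = w[e];
    }
  }
  const int s = src - 1, t = dst - 1;
  std::vector<char> edge_off(m, 0), node_off(n, 0);
  std::vector<Candidate> A;
  std::set<Candidate> B;
  std::set<std::vector<int> > seen;

  Candidate first;
  if (!dijkstra(g, s, t, edge_off, node_off, first.path, first.cost))
    return List::create(_["paths"] = List(0),
                        _["costs"] = NumericVector(0));
  A.push_back(first);
  seen.insert(first.path);

  while ((int)A.size() < k) {
    const std::vector<int> &prev = A.back().path;
    for (size_t i = 0; i + 1 < prev.size(); ++i) {
      int spur = prev[i];
      std::vector<int> root(prev.begin(), prev.begin() + i + 1);
      double root_cost = 0.0;
      bool root_ok = true;
      for (size_t j = 0; j + 1 < root.size(); ++j) {
        bool found = false;
        for (int e = g.head[root[j]]; e < g.head[root[j] + 1]; ++e)
          if (g.to[e] == root[j + 1]) { root_cost += g.w[e]; found = true; break; }
        if (!found) { root_ok = false; break; }
      }
      if (!root_ok) continue;
      std::fill(edge_off.begin(), edge_off.end(), 0);
      std::fill(node_off.begin(), node_off.end(), 0);
      // block edges used by accepted/candidate-sharing paths with this root
      for (const Candidate &p : A) {
        if (p.path.size() <= i + 1) continue;
        if (!std::equal(root.begin(), root.end(), p.path.begin())) continue;
        int u = p.path[i], v = p.path[i + 1];
        for (int e = g.head[u]; e < g.head[u + 1]; ++e)
          if (g.to[e] == v) edge_off[e] = 1;
      }
      for (size_t j = 0; j + 1 < root.size(); ++j) node_off[root[j]] = 1;
      Candidate cand;
      std::vector<int> spur_path;
      double spur_cost;
      if (!dijkstra(g, spur, t, edge_off, node_off, spur_path, spur_cost))
        continue;
      cand.path = root;
      cand.path.pop_back();
      cand.path.insert(cand.path.end(), spur_path.begin(), spur_path.end());
      cand.cost = root_cost + spur_cost;
      if (seen.find(cand.path) == seen.end()) {
        B.insert(cand);
        seen.insert(cand.path);
      }
    }
    if (B.empty()) break;
    A.push_back(*B.begin());
    B.erase(B.begin());
  }
  std::sort(A.begin(), A.end());
  List paths(A.size());
  NumericVector costs(A.size());
  for (size_t i = 0; i < A.size(); ++i) {
    IntegerVector p(A[i].path.size());
    for (size_t j = 0; j < A[i].path.size(); ++j) p[j] = A[i].path[j] + 1;
    paths[i] = p;
    costs[i] = A[i].cost;
  }
  return List::create(_["paths"] = paths, _["costs"] = costs);
}
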