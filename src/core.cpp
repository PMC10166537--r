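#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Pairwise distances between rows of tangent coordinates X (n x d).
// kappa < 0: points are projected onto the hyperboloid sheet (x0 = sqrt(1+|u|^2))
// and d = acosh(-<x,y>_L) / sqrt(-kappa), with the acosh argument clamped to >= 1.
// kappa == 0: plain Euclidean distances between tangent rows.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_distances(NumericMatrix X, double kappa) {
  const int n = X.nrow(), d = X.ncol();
  NumericMatrix D(n, n);
  if (kappa == 0.0) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double t = X(i, k) - X(j, k);
          s += t * t;
        }
        D(i, j) = D(j, i) = std::sqrt(s);
      }
    return D;
  }
  const double sk = std::sqrt(-kappa);
  std::vector<double> x0(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;
    for (int k = 0; k < d; ++k) s += X(i, k) * X(i, k);
    x0[i] = std::sqrt(s);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += X(i, k) * X(j, k);
      double c = x0[i] * x0[j] - dot; // = -<x,y>_L
      if (c < 1.0) c = 1.0;
      double dist = std::acosh(c) / sk;
      D(i, j) = D(j, i) = dist;
    }
  return D;
}

// Neighbour joining with deterministic lexicographic tie-breaking and
// branch lengths clamped at zero. Tips are nodes 1..n; internal nodes are
// created as n+1, ..., 2n-2 in agglomeration order. Returns the 2n-3 edges
// (undirected) and their lengths.
// [[Rcpp::export]]
List cpp_nj(NumericMatrix D) {
  const int n = D.nrow();
  if (n < 3) stop("neighbour joining requires at least 3 taxa");
  const int total = 2 * n - 2, m = 2 * n - 3;
  // working distances over all (eventual) nodes
  std::vector<double> M((size_t)total * total, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) M[(size_t)i * total + j] = D(i, j);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i; // 0-based ids
  IntegerMatrix edge(m, 2);
  NumericVector elen(m);
  int e = 0, next_id = n;
  int r = n;
  while (r > 3) {
    std::vector<double> R(r, 0.0);
    for (int a = 0; a < r; ++a) {
      double s = 0.0;
      for (int b = 0; b < r; ++b) s += M[(size_t)act[a] * total + act[b]];
      R[a] = s;
    }
    double qmin = R_PosInf;
    int bi = -1, bj = -1;
    for (int a = 0; a < r; ++a)
      for (int b = a + 1; b < r; ++b) {
        double q = (r - 2) * M[(size_t)act[a] * total + act[b]] - R[a] - R[b];
        if (q < qmin) { qmin = q; bi = a; bj = b; }
      }
    const int i = act[bi], j = act[bj];
    const double dij = M[(size_t)i * total + j];
    double li = 0.5 * dij + (R[bi] - R[bj]) / (2.0 * (r - 2));
    double lj = dij - li;
    if (li < 0.0) li = 0.0;
    if (lj < 0.0) lj = 0.0;
    const int u = next_id++;
    for (int a = 0; a < r; ++a) {
      int k = act[a];
      if (k == i || k == j) continue;
      double duk = 0.5 * (M[(size_t)i * total + k] + M[(size_t)j * total + k] - dij);
      if (duk < 0.0) duk = 0.0;
      M[(size_t)u * total + k] = duk;
      M[(size_t)k * total + u] = duk;
    }
    edge(e, 0) = u + 1; edge(e, 1) = i + 1; elen[e] = li; ++e;
    edge(e, 0) = u + 1; edge(e, 1) = j + 1; elen[e] = lj; ++e;
    // remove i, j; append u (act stays sorted: u exceeds all current ids)
    std::vector<int> nact;
    nact.reserve(r - 1);
    for (int a = 0; a < r; ++a)
      if (a != bi && a != bj) nact.push_back(act[a]);
    nact.push_back(u);
    act.swap(nact);
    r--;
  }
  // final trifurcation
  const int a = act[0], b = act[1], c = act[2], u = next_id++;
  const double dab = M[(size_t)a * total + b], dac = M[(size_t)a * total + c],
               dbc = M[(size_t)b * total + c];
  double la = 0.5 * (dab + dac - dbc);
  double lb = 0.5 * (dab + dbc - dac);
  double lc = 0.5 * (dac + dbc - dab);
  if (la < 0.0) la = 0.0;
  if (lb < 0.0) lb = 0.0;
  if (lc < 0.0) lc = 0.0;
  edge(e, 0) = u + 1; edge(e, 1) = a + 1; elen[e] = la; ++e;
  edge(e, 0) = u + 1; edge(e, 1) = b + 1; elen[e] = lb; ++e;
  edge(e, 0) = u + 1; edge(e, 1) = c + 1; elen[e] = lc; ++e;
  return List::create(_["edge"] = edge, _["edge_length"] = elen,
                      _["n_tip"] = n);
}

// JC69 log-likelihood by Felsenstein pruning over site patterns.
// edge: undirected edge list (1-based node ids, tips 1..ntip), edge_length
// in expected substitutions per site, codes: ntip x npat integer matrix with
// 0 = missing and 1..4 = A,C,G,T, weights: pattern counts. Uniform base
// frequencies. The traversal is rooted at an arbitrary internal node; by
// reversibility the choice does not affect the result.
// [[Rcpp::export]]
double cpp_jc69_loglik(IntegerMatrix edge, NumericVector edge_length,
                       IntegerMatrix codes, NumericVector weights) {
  const int ntip = codes.nrow(), npat = codes.ncol(), m = edge.nrow();
  int total = ntip;
  for (int e = 0; e < m; ++e)
    total = std::max(total, std::max(edge(e, 0), edge(e, 1)));
  // adjacency
  std::vector<std::vector<std::pair<int, double>>> adj(total + 1);
  for (int e = 0; e < m; ++e) {
    int a = edge(e, 0), b = edge(e, 1);
    adj[a].push_back({b, edge_length[e]});
    adj[b].push_back({a, edge_length[e]});
  }
  int root = ntip + 1; // guaranteed internal for any tree with >= 3 tips
  // iterative post-order
  std::vector<int> order, stack_node, stack_par, parent(total + 1, 0);
  std::vector<double> parlen(total + 1, 0.0);
  stack_node.push_back(root);
  stack_par.push_back(0);
  while (!stack_node.empty()) {
    int v = stack_node.back(); stack_node.pop_back();
    int p = stack_par.back(); stack_par.pop_back();
    parent[v] = p;
    order.push_back(v);
    for (auto &nb : adj[v])
      if (nb.first != p) {
        stack_node.push_back(nb.first);
        stack_par.push_back(v);
        parlen[nb.first] = nb.second;
      }
  }
  std::vector<double> part((size_t)(total + 1) * npat * 4);
  // process in reverse preorder = post-order
  for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
    int v = order[idx];
    double *pv = &part[(size_t)v * npat * 4];
    if (v <= ntip) {
      for (int s = 0; s < npat; ++s) {
        int c = codes(v - 1, s);
        double *q = pv + (size_t)s * 4;
        if (c == 0) { q[0] = q[1] = q[2] = q[3] = 1.0; }
        else { q[0] = q[1] = q[2] = q[3] = 0.0; q[c - 1] = 1.0; }
      }
    } else {
      for (int s = 0; s < npat * 4; ++s) pv[s] = 1.0;
      for (auto &nb : adj[v]) {
        int w = nb.first;
        if (w == parent[v]) continue;
        double t = parlen[w];
        double ex = std::exp(-4.0 * t / 3.0);
        double psame = 0.25 + 0.75 * ex, pdiff = 0.25 - 0.25 * ex;
        double *pw = &part[(size_t)w * npat * 4];
        for (int s = 0; s < npat; ++s) {
          double *cw = pw + (size_t)s * 4;
          double S = cw[0] + cw[1] + cw[2] + cw[3];
          double *q = pv + (size_t)s * 4;
          for (int a = 0; a < 4; ++a)
            q[a] *= pdiff * S + (psame - pdiff) * cw[a];
        }
      }
    }
  }
  double ll = 0.0;
  double *pr = &part[(size_t)root * npat * 4];
  for (int s = 0; s < npat; ++s) {
    double *q = pr + (size_t)s * 4;
    double L = 0.25 * (q[0] + q[1] + q[2] + q[3]);
    ll += weights[s] * std::log(L);
  }
  return ll;
}

// One embedding-to-scored-tree decode: pairwise hyperbolic (or Euclidean)
// distances, NJ, pruning log-likelihood. The per-generation workhorse.
// [[Rcpp::export]]
List cpp_decode_state(NumericMatrix X, double kappa, IntegerMatrix codes,
                      NumericVector weights) {
  NumericMatrix D = cpp_pairwise_distances(X, kappa);
  List nj = cpp_nj(D);
  IntegerMatrix edge = nj["edge"];
  NumericVector elen = nj["edge_length"];
  double ll = cpp_jc69_loglik(edge, elen, codes, weights);
  return List::create(_["edge"] = edge, _["edge_length"] = elen,
                      _["loglik"] = ll);
}
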