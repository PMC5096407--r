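#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>
using namespace Rcpp;

// Unrooted binary trees over tips 1..nTip and internal nodes
// nTip+1 .. 2*nTip-2 (ape "unrooted" numbering: the node adjacent to the
// basal trichotomy carries id nTip+1).  All heavy loops work on a plain
// adjacency structure; character states are bitmasks (bit j = state j),
// with missing/inapplicable/variable cells carrying the full observed-state
// mask of their column so that they can never add steps.

struct Adj {
  int M;
  std::vector<std::array<int, 3>> nb;
  std::vector<int> deg;
  explicit Adj(int M_) : M(M_), nb(M_ + 1), deg(M_ + 1, 0) {}
  void add(int a, int b) {
    if (deg[a] > 2 || deg[b] > 2) stop("internal error: node degree > 3");
    nb[a][deg[a]++] = b;
    nb[b][deg[b]++] = a;
  }
  void rm1(int a, int b) {
    for (int i = 0; i < deg[a]; ++i)
      if (nb[a][i] == b) {
        nb[a][i] = nb[a][deg[a] - 1];
        --deg[a];
        return;
      }
    stop("internal error: edge not found");
  }
  void rm(int a, int b) { rm1(a, b); rm1(b, a); }
  bool has_edge(int a, int b) const {
    for (int i = 0; i < deg[a]; ++i)
      if (nb[a][i] == b) return true;
    return false;
  }
};

static Adj adj_from_edge(const IntegerMatrix &edge, int nTip) {
  int M = 2 * nTip - 2;
  Adj A(M);
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    if (a < 1 || a > M || b < 1 || b > M) stop("edge matrix refers to node outside 1..2n-2");
    A.add(a, b);
  }
  return A;
}

// Re-emit an adjacency as an ape-style edge matrix: root the tree at the
// internal node adjacent to tip 1, relabel internal nodes in preorder
// starting at nTip+1.
static IntegerMatrix adj_to_edge(const Adj &A, int nTip) {
  int M = 2 * nTip - 2;
  std::vector<int> newid(M + 1, 0);
  for (int t = 1; t <= nTip; ++t) newid[t] = t;
  int root = A.nb[1][0];
  int nextid = nTip + 1;
  IntegerMatrix edge(2 * nTip - 3, 2);
  int row = 0;
  std::vector<std::pair<int, int>> stack;  // (node, parent)
  stack.push_back({root, 0});
  while (!stack.empty()) {
    auto pr = stack.back();
    stack.pop_back();
    int x = pr.first, p = pr.second;
    if (x > nTip) newid[x] = nextid++;
    if (p != 0) {
      edge(row, 0) = newid[p];
      edge(row, 1) = newid[x];
      ++row;
    }
    for (int i = A.deg[x] - 1; i >= 0; --i) {
      int y = A.nb[x][i];
      if (y != p) stack.push_back({y, x});
    }
  }
  if (row != 2 * nTip - 3) stop("internal error: adjacency is not a tree");
  return edge;
}

// ---------------------------------------------------------------------------
// Fitch scoring
// ---------------------------------------------------------------------------

// Per-character Fitch step counts for the unrooted binary tree in A,
// rooted for traversal at tip `roottip`.  Tips outside the tree are simply
// never visited, so the same state matrix serves partial trees during
// stepwise addition.
static void fitch_counts_adj(const Adj &A, int nTip, const IntegerMatrix &st,
                             int roottip, std::vector<int> &counts) {
  int nc = st.ncol();
  counts.assign(nc, 0);
  int c0 = A.nb[roottip][0];
  // iterative postorder
  std::vector<int> order;
  order.reserve(A.M);
  std::vector<int> parent(A.M + 1, 0);
  std::vector<int> stack;
  stack.push_back(c0);
  parent[c0] = roottip;
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    order.push_back(x);
    for (int i = 0; i < A.deg[x]; ++i) {
      int y = A.nb[x][i];
      if (y != parent[x]) {
        parent[y] = x;
        stack.push_back(y);
      }
    }
  }
  std::vector<unsigned int> S((A.M + 1) * nc);
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int x = order[oi];
    unsigned int *Sx = &S[(size_t)x * nc];
    if (x <= nTip) {
      for (int c = 0; c < nc; ++c) Sx[c] = (unsigned int)st(x - 1, c);
    } else {
      int ch[2], nch = 0;
      for (int i = 0; i < A.deg[x]; ++i)
        if (A.nb[x][i] != parent[x]) ch[nch++] = A.nb[x][i];
      if (nch != 2) stop("fitch scoring requires a binary (fully resolved) tree");
      unsigned int *S1 = &S[(size_t)ch[0] * nc];
      unsigned int *S2 = &S[(size_t)ch[1] * nc];
      for (int c = 0; c < nc; ++c) {
        unsigned int in = S1[c] & S2[c];
        if (in) Sx[c] = in;
        else {
          Sx[c] = S1[c] | S2[c];
          ++counts[c];
        }
      }
    }
  }
  unsigned int *Sc0 = &S[(size_t)c0 * nc];
  for (int c = 0; c < nc; ++c)
    if (!(Sc0[c] & (unsigned int)st(roottip - 1, c))) ++counts[c];
}

// [[Rcpp::export]]
IntegerVector fitch_counts_cpp(IntegerMatrix edge, int nTip, IntegerMatrix states) {
  Adj A = adj_from_edge(edge, nTip);
  std::vector<int> counts;
  fitch_counts_adj(A, nTip, states, 1, counts);
  return wrap(counts);
}

// ---------------------------------------------------------------------------
// Branch collapsing support. An internal branch has "minimum length zero"
// when every character admits a minimum-change reconstruction with no
// change on that branch; such branches are collapsed before counting
// distinct optimal trees. Exact per-edge test via a two-pass unit-cost
// Sankoff dynamic programme.
// ---------------------------------------------------------------------------

// can_zero[x] (indexed by child node x of the tip-1-rooted orientation):
// true iff the edge above x can carry zero changes in some optimal
// reconstruction of every character. Only meaningful for internal splits.
static void collapse_can_zero(const Adj &A, int nTip, const IntegerMatrix &st,
                              std::vector<int> &parent, std::vector<int> &order,
                              std::vector<bool> &can_zero) {
  int M = A.M;
  int nc = st.ncol();
  const double INF = 1e9;
  parent.assign(M + 1, 0);
  order.clear();
  int c0 = A.nb[1][0];
  parent[c0] = 1;
  {
    std::vector<int> stack;
    stack.push_back(c0);
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      order.push_back(x);
      for (int i = 0; i < A.deg[x]; ++i) {
        int y = A.nb[x][i];
        if (y != parent[x]) {
          parent[y] = x;
          stack.push_back(y);
        }
      }
    }
  }
  can_zero.assign(M + 1, true);
  // union mask per character
  for (int ch = 0; ch < nc; ++ch) {
    unsigned int all = 0;
    for (int t = 1; t <= nTip; ++t)
      if (A.deg[t] > 0) all |= (unsigned int)st(t - 1, ch);
    std::vector<int> statev;
    for (int b = 0; b < 31; ++b)
      if (all & (1u << b)) statev.push_back(b);
    int ns = (int)statev.size();
    if (ns <= 1) continue;
    std::vector<double> D((size_t)(M + 1) * ns, 0.0);
    std::vector<double> TRM((size_t)(M + 1) * ns, 0.0);
    // postorder down-pass
    for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
      int x = order[oi];
      double *Dx = &D[(size_t)x * ns];
      if (x <= nTip) {
        unsigned int mask = (unsigned int)st(x - 1, ch);
        for (int s = 0; s < ns; ++s)
          Dx[s] = (mask & (1u << statev[s])) ? 0.0 : INF;
      } else {
        for (int s = 0; s < ns; ++s) Dx[s] = 0.0;
        for (int i = 0; i < A.deg[x]; ++i) {
          int y = A.nb[x][i];
          if (y == parent[x]) continue;
          double *Dy = &D[(size_t)y * ns];
          double *Ty = &TRM[(size_t)y * ns];
          double mn = INF;
          for (int s = 0; s < ns; ++s) mn = std::min(mn, Dy[s]);
          for (int s = 0; s < ns; ++s) {
            Ty[s] = std::min(Dy[s], mn + 1.0);
            Dx[s] += Ty[s];
          }
        }
      }
    }
    // total optimum, folding tip 1
    double L = INF;
    {
      unsigned int mask1 = (unsigned int)st(0, ch);
      double *Dc = &D[(size_t)c0 * ns];
      double mn = INF;
      for (int s = 0; s < ns; ++s) mn = std::min(mn, Dc[s]);
      for (int s = 0; s < ns; ++s)
        if (mask1 & (1u << statev[s]))
          L = std::min(L, std::min(Dc[s], mn + 1.0));
    }
    // preorder up-pass; U[x][y] = cost outside subtree(x) given x = y
    std::vector<double> U((size_t)(M + 1) * ns, 0.0);
    {
      unsigned int mask1 = (unsigned int)st(0, ch);
      double *Uc = &U[(size_t)c0 * ns];
      // OUT for c0 given parent (tip 1) state y
      double outmn = INF;
      std::vector<double> OUT(ns);
      for (int s = 0; s < ns; ++s) {
        OUT[s] = (mask1 & (1u << statev[s])) ? 0.0 : INF;
        outmn = std::min(outmn, OUT[s]);
      }
      double *Dc = &D[(size_t)c0 * ns];
      if (c0 > nTip) {
        double zmin = INF;
        for (int s = 0; s < ns; ++s) zmin = std::min(zmin, OUT[s] + Dc[s]);
        if (zmin > L + 1e-9) can_zero[c0] = false;
      }
      for (int s = 0; s < ns; ++s) Uc[s] = std::min(OUT[s], outmn + 1.0);
    }
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int p = order[oi];
      if (p <= nTip) continue;
      double *Upv = &U[(size_t)p * ns];
      double *Dp = &D[(size_t)p * ns];
      for (int i = 0; i < A.deg[p]; ++i) {
        int k = A.nb[p][i];
        if (k == parent[p]) continue;
        double *Tk = &TRM[(size_t)k * ns];
        double *Dk = &D[(size_t)k * ns];
        double *Uk = &U[(size_t)k * ns];
        double outmn = INF, zmin = INF;
        for (int s = 0; s < ns; ++s) {
          double out = Dp[s] + Upv[s] - Tk[s];
          Uk[s] = out;  // temporarily OUT
          outmn = std::min(outmn, out);
          zmin = std::min(zmin, out + Dk[s]);
        }
        if (k > nTip && zmin > L + 1e-9) can_zero[k] = false;
        for (int s = 0; s < ns; ++s) Uk[s] = std::min(Uk[s], outmn + 1.0);
      }
    }
  }
}

// [[Rcpp::export]]
LogicalVector collapse_mask_cpp(IntegerMatrix edge, int nTip,
                                IntegerMatrix states) {
  Adj A = adj_from_edge(edge, nTip);
  std::vector<int> parent, order;
  std::vector<bool> can_zero;
  collapse_can_zero(A, nTip, states, parent, order, can_zero);
  LogicalVector out(edge.nrow());
  for (int r = 0; r < edge.nrow(); ++r) {
    int c = edge(r, 1);
    out[r] = (c > nTip) && can_zero[c];
  }
  return out;
}

// FNV-1a over a byte view
static inline unsigned long long fnv1a(unsigned long long h,
                                       unsigned long long v) {
  for (int i = 0; i < 8; ++i) {
    h ^= (v >> (8 * i)) & 0xffull;
    h *= 1099511628211ull;
  }
  return h;
}

// Topology hash with optional min-length-zero collapsing: sorted hashes of
// the non-trivial retained splits, folded into one 64-bit value.
static std::string hash_internal(const Adj &A, int nTip,
                                 const std::vector<int> &parent,
                                 const std::vector<int> &order,
                                 const std::vector<bool> *keep_child) {
  int nW = (nTip + 63) / 64;
  std::vector<std::vector<unsigned long long>> below(
      A.M + 1, std::vector<unsigned long long>(nW, 0ull));
  std::vector<unsigned long long> keys;
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int x = order[oi];
    if (x <= nTip) {
      below[x][(x - 1) / 64] |= (1ull << ((x - 1) % 64));
    } else {
      for (int i = 0; i < A.deg[x]; ++i) {
        int y = A.nb[x][i];
        if (y != parent[x])
          for (int wdx = 0; wdx < nW; ++wdx) below[x][wdx] |= below[y][wdx];
      }
    }
    if (x <= nTip || parent[x] == 1) continue;
    int sz = 0;
    for (int wdx = 0; wdx < nW; ++wdx)
      sz += __builtin_popcountll(below[x][wdx]);
    if (sz < 2 || sz > nTip - 2) continue;
    if (keep_child && (*keep_child)[x]) continue;  // collapsible edge
    unsigned long long h = 1469598103934665603ull;
    for (int wdx = 0; wdx < nW; ++wdx) h = fnv1a(h, below[x][wdx]);
    keys.push_back(h);
  }
  std::sort(keys.begin(), keys.end());
  unsigned long long h = 1469598103934665603ull;
  for (auto k : keys) h = fnv1a(h, k);
  char buf[32];
  snprintf(buf, sizeof(buf), "%016llx", h);
  return std::string(buf);
}

// [[Rcpp::export]]
std::string collapsed_hash_cpp(IntegerMatrix edge, int nTip,
                               IntegerMatrix states) {
  Adj A = adj_from_edge(edge, nTip);
  std::vector<int> parent, order;
  std::vector<bool> can_zero;
  collapse_can_zero(A, nTip, states, parent, order, can_zero);
  return hash_internal(A, nTip, parent, order, &can_zero);
}

// Canonical topology hash of an unrooted binary tree (no collapsing).
// [[Rcpp::export]]
std::string tree_hash_cpp(IntegerMatrix edge, int nTip) {
  Adj A = adj_from_edge(edge, nTip);
  std::vector<int> parent(A.M + 1, 0), order;
  order.reserve(A.M);
  int c0 = A.nb[1][0];
  parent[c0] = 1;
  std::vector<int> stack;
  stack.push_back(c0);
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    order.push_back(x);
    for (int i = 0; i < A.deg[x]; ++i) {
      int y = A.nb[x][i];
      if (y != parent[x]) {
        parent[y] = x;
        stack.push_back(y);
      }
    }
  }
  return hash_internal(A, nTip, parent, order, nullptr);
}

// Scorer for partial trees during branch and bound: the edge list spans a
// subset of tips (tip 1 must be placed); nodes absent from the edge list
// are simply never visited.
// [[Rcpp::export]]
IntegerVector fitch_counts_partial_cpp(IntegerMatrix edge, int nTip,
                                       IntegerMatrix states) {
  int M = 2 * nTip - 2;
  Adj A(M);
  for (int i = 0; i < edge.nrow(); ++i) A.add(edge(i, 0), edge(i, 1));
  if (A.deg[1] == 0) stop("tip 1 must be part of the partial tree");
  std::vector<int> counts;
  fitch_counts_adj(A, nTip, states, 1, counts);
  return wrap(counts);
}

// ---------------------------------------------------------------------------
// Objective helpers: equal weights minimise sum(w_i * s_i); implied
// weighting minimises sum(e_i / (k + e_i)) with e_i = s_i - m_i, which
// orders trees identically to maximising the Goloboff fit F = sum k/(k+e).
// ---------------------------------------------------------------------------

static double objective_from_counts(const std::vector<int> &counts,
                                    const NumericVector &w, bool iw, double k,
                                    const IntegerVector &minsteps) {
  double s = 0.0;
  if (!iw) {
    for (size_t i = 0; i < counts.size(); ++i) s += w[i] * counts[i];
  } else {
    for (size_t i = 0; i < counts.size(); ++i) {
      double e = counts[i] - minsteps[i];
      if (e < 0) e = 0;  // partial trees during stepwise addition
      s += e / (k + e);
    }
  }
  return s;
}

// ---------------------------------------------------------------------------
// Random addition sequence: greedy stepwise insertion in the supplied taxon
// order, each taxon placed on the branch giving the lowest objective score
// (first-encountered branch wins ties, so the result is deterministic given
// the order).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix ras_tree_cpp(IntegerVector order, IntegerMatrix states,
                           NumericVector w, bool iw, double k,
                           IntegerVector minsteps) {
  int nTip = states.nrow();
  if (order.size() != nTip) stop("order must be a permutation of 1..nTip");
  if (nTip < 4) stop("stepwise addition requires at least 4 taxa");
  int M = 2 * nTip - 2;
  Adj A(M);
  int roottip = order[0];
  int nextInternal = nTip + 1;
  A.add(order[0], nextInternal);
  A.add(order[1], nextInternal);
  A.add(order[2], nextInternal);
  ++nextInternal;
  std::vector<int> counts;
  std::vector<std::pair<int, int>> edges;
  for (int j = 3; j < nTip; ++j) {
    int t = order[j];
    // collect current edges
    edges.clear();
    for (int x = 1; x <= M; ++x)
      for (int i = 0; i < A.deg[x]; ++i)
        if (A.nb[x][i] > x) edges.push_back({x, A.nb[x][i]});
    int newInt = nextInternal;
    double bestScore = R_PosInf;
    std::pair<int, int> bestEdge = edges[0];
    for (auto &e : edges) {
      A.rm(e.first, e.second);
      A.add(e.first, newInt);
      A.add(e.second, newInt);
      A.add(t, newInt);
      fitch_counts_adj(A, nTip, states, roottip, counts);
      double s = objective_from_counts(counts, w, iw, k, minsteps);
      A.rm(t, newInt);
      A.rm(e.first, newInt);
      A.rm(e.second, newInt);
      A.add(e.first, e.second);
      if (s < bestScore - 1e-12) {
        bestScore = s;
        bestEdge = e;
      }
    }
    A.rm(bestEdge.first, bestEdge.second);
    A.add(bestEdge.first, newInt);
    A.add(bestEdge.second, newInt);
    A.add(t, newInt);
    ++nextInternal;
  }
  return adj_to_edge(A, nTip);
}

// ---------------------------------------------------------------------------
// TBR sweep.
//
// For every bisection edge the two components are formed (contracting the
// degree-2 stump each side), per-character directional Fitch state sets are
// computed for every component edge, and every reconnection (one attachment
// edge per side) is scored in O(nchar) via
//     s_i(T') = U1_i + U2_i + [S1_i(e1) & S2_i(e2) == 0]
// where U_j are the per-character unrooted Fitch lengths of the components
// and S_j(e) is the Fitch state set of a degree-2 junction placed on edge e.
// ---------------------------------------------------------------------------

struct Component {
  bool single = false;           // component is a lone tip
  int singleTip = 0;
  std::vector<int> ea, eb;       // attachment edges (parent, child in DFS)
  std::vector<unsigned int> S;   // nedge * nc midpoint state sets
  std::vector<int> U;            // per-character component length
  int contracted = -1;           // index of the edge recreated by contraction
};

// Build the component on the `w` side of removed edge (u,v); cu,cv are the
// contraction partners (w's two remaining neighbours) when w is internal.
static void build_component(const Adj &A, int nTip, const IntegerMatrix &st,
                            int u, int v, int w, Component &C,
                            std::vector<int> &scratch_parent,
                            std::vector<unsigned int> &D,
                            std::vector<unsigned int> &Up) {
  int nc = st.ncol();
  int other = (w == u) ? v : u;
  C.ea.clear();
  C.eb.clear();
  C.U.assign(nc, 0);
  C.contracted = -1;
  C.single = false;
  if (w <= nTip) {  // pendant bisection: component is tip w
    C.single = true;
    C.singleTip = w;
    C.S.assign(nc, 0u);
    for (int c = 0; c < nc; ++c) C.S[c] = (unsigned int)st(w - 1, c);
    return;
  }
  // contraction partners of w
  int ca = -1, cb = -1;
  for (int i = 0; i < A.deg[w]; ++i) {
    int y = A.nb[w][i];
    if (y == other) continue;
    if (ca < 0) ca = y; else cb = y;
  }
  // local adjacency view: function giving neighbours of a node inside the
  // component with w contracted away
  auto neighbours = [&](int x, std::array<int, 3> &out) -> int {
    int n = 0;
    if (x == ca) out[n++] = cb;
    else if (x == cb) out[n++] = ca;
    for (int i = 0; i < A.deg[x]; ++i) {
      int y = A.nb[x][i];
      if (y == w) continue;
      out[n++] = y;
    }
    return n;
  };
  // find the smallest tip in the component by DFS from ca
  std::vector<int> &parent = scratch_parent;
  // DFS collecting preorder
  static thread_local std::vector<int> order;
  order.clear();
  std::array<int, 3> nbx;
  int r = -1;
  {
    std::vector<int> stack;
    stack.push_back(ca);
    parent[ca] = 0;
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      if (x <= nTip && (r < 0 || x < r)) r = x;
      order.push_back(x);
      int n = neighbours(x, nbx);
      for (int i = 0; i < n; ++i)
        if (nbx[i] != parent[x]) {
          parent[nbx[i]] = x;
          stack.push_back(nbx[i]);
        }
    }
  }
  // re-run DFS rooted at tip r for a clean parent/order
  order.clear();
  {
    std::vector<int> stack;
    int c0 = -1;
    std::array<int, 3> nbr;
    int n = neighbours(r, nbr);
    if (n != 1) stop("internal error: component tip degree != 1");
    c0 = nbr[0];
    parent[r] = 0;
    parent[c0] = r;
    stack.push_back(c0);
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      order.push_back(x);
      int nn = neighbours(x, nbx);
      for (int i = 0; i < nn; ++i)
        if (nbx[i] != parent[x]) {
          parent[nbx[i]] = x;
          stack.push_back(nbx[i]);
        }
    }
  }
  // postorder down-sets
  for (int oi = (int)order.size() - 1; oi >= 0; --oi) {
    int x = order[oi];
    unsigned int *Dx = &D[(size_t)x * nc];
    if (x <= nTip) {
      for (int c = 0; c < nc; ++c) Dx[c] = (unsigned int)st(x - 1, c);
    } else {
      int ch[2], nch = 0;
      int nn = neighbours(x, nbx);
      for (int i = 0; i < nn; ++i)
        if (nbx[i] != parent[x]) ch[nch++] = nbx[i];
      unsigned int *D1 = &D[(size_t)ch[0] * nc];
      unsigned int *D2 = &D[(size_t)ch[1] * nc];
      for (int c = 0; c < nc; ++c) {
        unsigned int in = D1[c] & D2[c];
        if (in) Dx[c] = in;
        else {
          Dx[c] = D1[c] | D2[c];
          ++C.U[c];
        }
      }
    }
  }
  // fold in the root tip
  {
    int c0 = order.empty() ? -1 : order[0];
    if (c0 > 0) {
      unsigned int *Dc = &D[(size_t)c0 * nc];
      for (int c = 0; c < nc; ++c)
        if (!(Dc[c] & (unsigned int)st(r - 1, c))) ++C.U[c];
    }
  }
  // preorder up-sets: Up[x] is the state set of everything on the parent
  // side of edge (parent[x], x)
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int x = order[oi];
    int p = parent[x];
    unsigned int *Ux = &Up[(size_t)x * nc];
    if (p == r) {
      for (int c = 0; c < nc; ++c) Ux[c] = (unsigned int)st(r - 1, c);
    } else {
      // p internal: other child of p is the sibling
      int sib = -1;
      int nn = neighbours(p, nbx);
      for (int i = 0; i < nn; ++i)
        if (nbx[i] != parent[p] && nbx[i] != x) sib = nbx[i];
      unsigned int *Upp = &Up[(size_t)p * nc];
      unsigned int *Ds = &D[(size_t)sib * nc];
      for (int c = 0; c < nc; ++c) {
        unsigned int in = Upp[c] & Ds[c];
        Ux[c] = in ? in : (Upp[c] | Ds[c]);
      }
    }
  }
  // attachment edges and their midpoint sets
  int ne = (int)order.size();
  C.S.assign((size_t)ne * nc, 0u);
  for (int oi = 0; oi < ne; ++oi) {
    int x = order[oi];
    int p = parent[x];
    C.ea.push_back(p);
    C.eb.push_back(x);
    if ((p == ca && x == cb) || (p == cb && x == ca)) C.contracted = oi;
    unsigned int *Sx = &C.S[(size_t)oi * nc];
    unsigned int *Ux = &Up[(size_t)x * nc];
    unsigned int *Dx = &D[(size_t)x * nc];
    for (int c = 0; c < nc; ++c) {
      unsigned int in = Ux[c] & Dx[c];
      Sx[c] = in ? in : (Ux[c] | Dx[c]);
    }
  }
}

// Rebuild the neighbour produced by bisecting (u,v) and reattaching side-1
// at (a1,b1) and side-2 at (a2,b2) (a*=0 for a single-tip side).
static IntegerMatrix rebuild_neighbor(const Adj &A0, int nTip, int u, int v,
                                      int a1, int b1, int a2, int b2) {
  Adj A = A0;  // copy
  A.rm(u, v);
  if (u > nTip) {
    int ca = A.nb[u][0], cb = A.nb[u][1];
    A.rm(u, ca);
    A.rm(u, cb);
    A.add(ca, cb);
  }
  if (v > nTip) {
    int ca = A.nb[v][0], cb = A.nb[v][1];
    A.rm(v, ca);
    A.rm(v, cb);
    A.add(ca, cb);
  }
  if (a1 > 0) {
    A.rm(a1, b1);
    A.add(a1, u);
    A.add(b1, u);
  }
  if (a2 > 0) {
    A.rm(a2, b2);
    A.add(a2, v);
    A.add(b2, v);
  }
  A.add(u, v);
  return adj_to_edge(A, nTip);
}

// restrict: 0 = full TBR, 1 = SPR only (one side must keep its original
// attachment edge, i.e. use the contracted edge or be a lone tip).
// [[Rcpp::export]]
List tbr_sweep_cpp(IntegerMatrix edge, int nTip, IntegerMatrix states,
                   NumericVector w, bool iw, double k, IntegerVector minsteps,
                   double cutoff, bool collect, int maxcollect,
                   int restrict_moves) {
  int nc = states.ncol();
  Adj A = adj_from_edge(edge, nTip);
  int M = A.M;
  double eps = 1e-9;
  double best = R_PosInf;
  std::vector<IntegerMatrix> trees;
  std::vector<double> scores;
  std::vector<int> scratch_parent(M + 1, 0);
  std::vector<unsigned int> D1v((size_t)(M + 1) * nc), U1v((size_t)(M + 1) * nc);
  std::vector<unsigned int> D2v((size_t)(M + 1) * nc), U2v((size_t)(M + 1) * nc);
  Component C1, C2;
  std::vector<double> d(nc);
  // enumerate bisection edges once
  std::vector<std::pair<int, int>> bis;
  for (int x = 1; x <= M; ++x)
    for (int i = 0; i < A.deg[x]; ++i)
      if (A.nb[x][i] > x) bis.push_back({x, A.nb[x][i]});
  for (auto &bv : bis) {
    int u = bv.first, v = bv.second;
    build_component(A, nTip, states, u, v, u, C1, scratch_parent, D1v, U1v);
    build_component(A, nTip, states, u, v, v, C2, scratch_parent, D2v, U2v);
    // unified per-character increments
    double sum0 = 0.0;
    for (int c = 0; c < nc; ++c) {
      int base = (C1.single ? 0 : C1.U[c]) + (C2.single ? 0 : C2.U[c]);
      if (!iw) {
        sum0 += w[c] * base;
        d[c] = w[c];
      } else {
        double e0 = base - minsteps[c];
        if (e0 < 0) e0 = 0;
        double e1 = base + 1 - minsteps[c];
        if (e1 < 0) e1 = 0;
        double f0 = e0 / (k + e0), f1 = e1 / (k + e1);
        sum0 += f0;
        d[c] = f1 - f0;
      }
    }
    int ne1 = C1.single ? 1 : (int)C1.ea.size();
    int ne2 = C2.single ? 1 : (int)C2.ea.size();
    for (int i1 = 0; i1 < ne1; ++i1) {
      const unsigned int *S1 =
          C1.single ? C1.S.data() : &C1.S[(size_t)i1 * nc];
      bool orig1 = C1.single || i1 == C1.contracted;
      for (int i2 = 0; i2 < ne2; ++i2) {
        bool orig2 = C2.single || i2 == C2.contracted;
        if (orig1 && orig2) continue;  // recreates the input tree
        if (restrict_moves == 1 && !orig1 && !orig2) continue;  // SPR
        const unsigned int *S2 =
            C2.single ? C2.S.data() : &C2.S[(size_t)i2 * nc];
        double s = sum0;
        for (int c = 0; c < nc; ++c)
          if (!(S1[c] & S2[c])) s += d[c];
        if (s < best) best = s;
        if (collect && s <= cutoff + eps && (int)trees.size() < maxcollect) {
          int a1 = C1.single ? 0 : C1.ea[i1];
          int b1 = C1.single ? 0 : C1.eb[i1];
          int a2 = C2.single ? 0 : C2.ea[i2];
          int b2 = C2.single ? 0 : C2.eb[i2];
          trees.push_back(rebuild_neighbor(A, nTip, u, v, a1, b1, a2, b2));
          scores.push_back(s);
        }
      }
    }
  }
  List treeList(trees.size());
  for (size_t i = 0; i < trees.size(); ++i) treeList[i] = trees[i];
  return List::create(_["best"] = best, _["trees"] = treeList,
                      _["scores"] = wrap(scores));
}
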