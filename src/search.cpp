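// Weighted binary-character parsimony on unrooted trees, with stepwise
// addition, NNI/SPR/TBR branch swapping, plateau harvesting of equally
// parsimonious trees, and exhaustive branch-and-bound enumeration.
//
// Character states are bitmasks: 1 = state 0 allowed, 2 = state 1 allowed,
// 3 = missing (both).  Weights are pre-scaled integers (exact rationals are
// handled on the R side); scores are integer step counts times weights.
// Because all characters are binary, the Sankoff two-state recursion is
// exact on multifurcating trees as well.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <algorithm>
#include <random>
#include <set>
#include <deque>
#include <cstdint>

using namespace Rcpp;

static const int BIGC = 1000000; // effectively infinite step count

struct CharMatrix {
  int m;                       // taxa (rows)
  int k;                       // characters
  std::vector<uint8_t> st;     // m*k, row-major by taxon
  std::vector<long long> w;    // scaled integer weights
  uint8_t at(int tip, int c) const { return st[(size_t)tip * k + c]; }
};

// leaf step penalty for assigning state s at a tip with allowance mask
static inline int leafpen(uint8_t mask, int s) {
  return ((mask >> s) & 1) ? 0 : 1;
}

struct UTree {
  int m;                             // taxon slots: tips are 0..m-1
  int cap;
  std::vector<std::array<int, 3>> adj;
  std::vector<int> deg;
  int next_internal;
  UTree(int m_) : m(m_) {
    cap = 2 * m_;                    // slack beyond 2m-2
    adj.assign(cap, {-1, -1, -1});
    deg.assign(cap, 0);
    next_internal = m_;
  }
  void add_edge(int a, int b) {
    adj[a][deg[a]++] = b;
    adj[b][deg[b]++] = a;
  }
  void drop_half(int a, int b) {
    for (int i = 0; i < deg[a]; ++i)
      if (adj[a][i] == b) { adj[a][i] = adj[a][--deg[a]]; adj[a][deg[a]] = -1; return; }
  }
  void remove_edge(int a, int b) { drop_half(a, b); drop_half(b, a); }
  bool has_edge(int a, int b) const {
    for (int i = 0; i < deg[a]; ++i) if (adj[a][i] == b) return true;
    return false;
  }
  int n_tips_present() const {
    int c = 0;
    for (int i = 0; i < m; ++i) if (deg[i] > 0) ++c;
    return c;
  }
};

// ------------------------------------------------------------------
// Full-tree score (used by stepwise addition fallback, NNI, validation)
// ------------------------------------------------------------------

static long long score_full(const UTree &T, const CharMatrix &M,
                            std::vector<int> *steps_out = nullptr) {
  int k = M.k;
  // find a present tip to serve as the scoring root's parent
  int rt = -1;
  for (int i = 0; i < T.m; ++i) if (T.deg[i] > 0) { rt = i; break; }
  if (rt < 0) return 0;
  int root = T.adj[rt][0];
  if (root < T.m) {
    // two-tip tree
    long long tot = 0;
    for (int c = 0; c < k; ++c) {
      int s = (M.at(rt, c) & M.at(root, c)) ? 0 : 1;
      if (steps_out) (*steps_out)[c] = s;
      tot += M.w[c] * s;
    }
    return tot;
  }
  // preorder from root, parent = rt
  std::vector<int> pre, parent(T.cap, -1);
  pre.reserve(T.cap);
  pre.push_back(root);
  parent[root] = rt;
  for (size_t qi = 0; qi < pre.size(); ++qi) {
    int nd = pre[qi];
    for (int i = 0; i < T.deg[nd]; ++i) {
      int nb = T.adj[nd][i];
      if (nb != parent[nd]) { parent[nb] = nd; pre.push_back(nb); }
    }
  }
  static thread_local std::vector<int> C;
  C.assign((size_t)T.cap * 2 * k, 0);
  for (int qi = (int)pre.size() - 1; qi >= 0; --qi) {
    int nd = pre[qi];
    int *cn = &C[(size_t)nd * 2 * k];
    if (nd < T.m) {
      for (int c = 0; c < k; ++c) {
        uint8_t msk = M.at(nd, c);
        cn[2 * c] = (msk & 1) ? 0 : BIGC;
        cn[2 * c + 1] = (msk & 2) ? 0 : BIGC;
      }
    } else {
      for (int i = 0; i < T.deg[nd]; ++i) {
        int nb = T.adj[nd][i];
        if (nb == parent[nd]) continue;
        const int *cc = &C[(size_t)nb * 2 * k];
        for (int c = 0; c < k; ++c) {
          int a = cc[2 * c], b = cc[2 * c + 1];
          cn[2 * c] += std::min(a, b + 1);
          cn[2 * c + 1] += std::min(b, a + 1);
        }
      }
    }
  }
  long long tot = 0;
  const int *cr = &C[(size_t)root * 2 * k];
  for (int c = 0; c < k; ++c) {
    uint8_t msk = M.at(rt, c);
    int v = std::min(cr[2 * c] + leafpen(msk, 0), cr[2 * c + 1] + leafpen(msk, 1));
    if (steps_out) (*steps_out)[c] = v;
    tot += M.w[c] * v;
  }
  return tot;
}

// ------------------------------------------------------------------
// Directed-edge DP: attachment-cost vectors for every edge of a component
// ------------------------------------------------------------------

struct Att {
  int p, c;          // edge endpoints (parent side, child side)
  int kind;          // 0 = real edge, 1 = virtual root edge, 2 = lone tip
  int off;           // offset into the shared E buffer (2k ints)
};

struct CompDP {
  std::vector<Att> atts;
  std::vector<int> E;      // attachment vectors, 2k per attachment
  int virtual_idx = -1;    // index into atts of the original attachment site
};

// Computes attachment vectors of the component reachable from `root`
// without crossing to `banned`.  If root is internal it is treated as a
// suppressed degree-2 node (TBR bisection); if it is a tip the component
// is the whole tree rooted at that tip.
static void compute_attachments(const UTree &T, const CharMatrix &M,
                                int root, int banned, CompDP &out) {
  int k = M.k;
  out.atts.clear();
  out.E.clear();
  out.virtual_idx = -1;

  if (root < T.m && (T.deg[root] == 0 ||
                     (T.deg[root] == 1 && T.adj[root][0] == banned))) {
    // lone tip component
    out.E.resize(2 * k);
    for (int c = 0; c < k; ++c) {
      uint8_t msk = M.at(root, c);
      out.E[2 * c] = (msk & 1) ? 0 : BIGC;
      out.E[2 * c + 1] = (msk & 2) ? 0 : BIGC;
    }
    out.atts.push_back({root, -1, 2, 0});
    out.virtual_idx = 0;
    return;
  }

  std::vector<int> pre, parent(T.cap, -2);
  pre.push_back(root);
  parent[root] = banned;
  for (size_t qi = 0; qi < pre.size(); ++qi) {
    int nd = pre[qi];
    for (int i = 0; i < T.deg[nd]; ++i) {
      int nb = T.adj[nd][i];
      if (nb != parent[nd]) { parent[nb] = nd; pre.push_back(nb); }
    }
  }

  static thread_local std::vector<int> Rd, Au;
  Rd.assign((size_t)T.cap * 2 * k, 0);
  Au.assign((size_t)T.cap * 2 * k, 0);

  // down pass (subtrees away from parent)
  for (int qi = (int)pre.size() - 1; qi >= 0; --qi) {
    int nd = pre[qi];
    int *rn = &Rd[(size_t)nd * 2 * k];
    if (nd < T.m) {
      for (int c = 0; c < k; ++c) {
        uint8_t msk = M.at(nd, c);
        rn[2 * c] = (msk & 1) ? 0 : BIGC;
        rn[2 * c + 1] = (msk & 2) ? 0 : BIGC;
      }
    } else {
      for (int i = 0; i < T.deg[nd]; ++i) {
        int nb = T.adj[nd][i];
        if (nb == parent[nd]) continue;
        const int *cc = &Rd[(size_t)nb * 2 * k];
        for (int c = 0; c < k; ++c) {
          int a = cc[2 * c], b = cc[2 * c + 1];
          rn[2 * c] += std::min(a, b + 1);
          rn[2 * c + 1] += std::min(b, a + 1);
        }
      }
    }
  }

  bool root_is_tip = (root < T.m);

  // up pass (component minus subtree, seen from the parent end of each edge)
  for (size_t qi = 0; qi < pre.size(); ++qi) {
    int p = pre[qi];
    for (int i = 0; i < T.deg[p]; ++i) {
      int c0 = T.adj[p][i];
      if (c0 == parent[p]) continue;
      int *ac = &Au[(size_t)c0 * 2 * k];
      if (p == root && root_is_tip) {
        for (int c = 0; c < k; ++c) {
          uint8_t msk = M.at(root, c);
          ac[2 * c] = (msk & 1) ? 0 : BIGC;
          ac[2 * c + 1] = (msk & 2) ? 0 : BIGC;
        }
        continue;
      }
      std::fill(ac, ac + 2 * k, 0);
      for (int j = 0; j < T.deg[p]; ++j) {
        int w = T.adj[p][j];
        if (w == c0 || w == parent[p]) continue;
        const int *cc = &Rd[(size_t)w * 2 * k];
        for (int c = 0; c < k; ++c) {
          int a = cc[2 * c], b = cc[2 * c + 1];
          ac[2 * c] += std::min(a, b + 1);
          ac[2 * c + 1] += std::min(b, a + 1);
        }
      }
      if (p != root) {
        const int *pp = &Au[(size_t)p * 2 * k];
        for (int c = 0; c < k; ++c) {
          int a = pp[2 * c], b = pp[2 * c + 1];
          ac[2 * c] += std::min(a, b + 1);
          ac[2 * c + 1] += std::min(b, a + 1);
        }
      }
    }
  }

  // attachment vectors
  auto push_att = [&](int p, int c, int kind) {
    int off = (int)out.E.size();
    out.E.resize(out.E.size() + 2 * k);
    out.atts.push_back({p, c, kind, off});
    return off;
  };

  bool suppress_root = !root_is_tip;   // bisection component: root had deg 2
  if (suppress_root) {
    // virtual edge joining the root's two children
    int a = -1, b = -1;
    for (int i = 0; i < T.deg[root]; ++i) {
      int nb = T.adj[root][i];
      if (nb == banned) continue;
      if (a < 0) a = nb; else b = nb;
    }
    int off = push_att(a, b, 1);
    out.virtual_idx = (int)out.atts.size() - 1;
    int *e = &out.E[off];
    const int *ra = &Rd[(size_t)a * 2 * k];
    const int *rb = &Rd[(size_t)b * 2 * k];
    for (int c = 0; c < k; ++c) {
      int a0 = ra[2 * c], a1 = ra[2 * c + 1];
      int b0 = rb[2 * c], b1 = rb[2 * c + 1];
      e[2 * c] = std::min(a0, a1 + 1) + std::min(b0, b1 + 1);
      e[2 * c + 1] = std::min(a1, a0 + 1) + std::min(b1, b0 + 1);
    }
  }
  for (size_t qi = 0; qi < pre.size(); ++qi) {
    int c0 = pre[qi];
    int p = parent[c0];
    if (c0 == root) continue;
    if (suppress_root && p == root) continue;  // replaced by the virtual edge
    int off = push_att(p, c0, 0);
    int *e = &out.E[off];
    const int *rd = &Rd[(size_t)c0 * 2 * k];
    const int *au = &Au[(size_t)c0 * 2 * k];
    for (int c = 0; c < k; ++c) {
      int d0 = rd[2 * c], d1 = rd[2 * c + 1];
      int u0 = au[2 * c], u1 = au[2 * c + 1];
      e[2 * c] = std::min(d0, d1 + 1) + std::min(u0, u1 + 1);
      e[2 * c + 1] = std::min(d1, d0 + 1) + std::min(u1, u0 + 1);
    }
  }
}

static long long pair_score(const int *E1, const int *E2,
                            const CharMatrix &M) {
  long long tot = 0;
  int k = M.k;
  for (int c = 0; c < k; ++c) {
    int a0 = E1[2 * c], a1 = E1[2 * c + 1];
    int b0 = E2[2 * c], b1 = E2[2 * c + 1];
    int v = std::min(a0 + std::min(b0, b1 + 1), a1 + std::min(b1, b0 + 1));
    tot += M.w[c] * v;
  }
  return tot;
}

// ------------------------------------------------------------------
// Tree edits
// ------------------------------------------------------------------

static void list_edges(const UTree &T, std::vector<std::pair<int, int>> &out) {
  out.clear();
  for (int a = 0; a < T.cap; ++a)
    for (int i = 0; i < T.deg[a]; ++i)
      if (a < T.adj[a][i]) out.emplace_back(a, T.adj[a][i]);
}

// detach the component of `u` created by removing edge (u,v) and reattach
// at attachment A1 (in u's component) / A2 (in v's component)
static void apply_tbr(UTree &T, int u, int v, const Att &A1, const Att &A2) {
  T.remove_edge(u, v);
  int end1, end2;
  if (A1.kind == 2) {
    end1 = A1.p;  // lone tip
  } else {
    int a = T.adj[u][0], b = T.adj[u][1];
    T.remove_edge(u, a);
    T.remove_edge(u, b);
    T.add_edge(a, b);
    T.remove_edge(A1.p, A1.c);
    T.add_edge(A1.p, u);
    T.add_edge(u, A1.c);
    end1 = u;
  }
  if (A2.kind == 2) {
    end2 = A2.p;
  } else {
    int a = T.adj[v][0], b = T.adj[v][1];
    T.remove_edge(v, a);
    T.remove_edge(v, b);
    T.add_edge(a, b);
    T.remove_edge(A2.p, A2.c);
    T.add_edge(A2.p, v);
    T.add_edge(v, A2.c);
    end2 = v;
  }
  T.add_edge(end1, end2);
}

static void insert_tip(UTree &T, int tip, int p, int q) {
  int w = T.next_internal++;
  T.remove_edge(p, q);
  T.add_edge(p, w);
  T.add_edge(w, q);
  T.add_edge(w, tip);
}

static void remove_last_tip(UTree &T, int tip) {
  int w = T.adj[tip][0];
  T.remove_edge(w, tip);
  int p = T.adj[w][0], q = T.adj[w][1];
  T.remove_edge(w, p);
  T.remove_edge(w, q);
  T.add_edge(p, q);
  T.next_internal--;
}

// ------------------------------------------------------------------
// Canonical rooted representation (outgroup as root)
// ------------------------------------------------------------------

static std::string canon_sub(const UTree &T, int node, int parent,
                             const std::vector<std::string> &labels) {
  if (node < T.m) return labels[node];
  std::vector<std::string> parts;
  for (int i = 0; i < T.deg[node]; ++i) {
    int nb = T.adj[node][i];
    if (nb != parent) parts.push_back(canon_sub(T, nb, node, labels));
  }
  std::sort(parts.begin(), parts.end());
  std::string s = "(";
  for (size_t i = 0; i < parts.size(); ++i) {
    if (i) s += ",";
    s += parts[i];
  }
  s += ")";
  return s;
}

// rooted ingroup newick: root at the outgroup's neighbour, outgroup dropped
static std::string rooted_newick(const UTree &T, int outgroup,
                                 const std::vector<std::string> &labels) {
  int root = T.adj[outgroup][0];
  return canon_sub(T, root, outgroup, labels) + ";";
}

// ------------------------------------------------------------------
// Sweeps
// ------------------------------------------------------------------

// One first-improvement sweep over the requested neighbourhood.
// Returns true (with T updated and cur lowered) on strict improvement.
static bool swap_sweep_improve(UTree &T, const CharMatrix &M, long long &cur,
                               int swap_kind /*0=NNI,1=SPR,2=TBR*/) {
  std::vector<std::pair<int, int>> edges;
  list_edges(T, edges);
  if (swap_kind == 0) {
    // NNI on internal edges, explicit construction
    for (auto &e : edges) {
      int u = e.first, v = e.second;
      if (u < T.m || v < T.m) continue;
      int nb_u[2], nu = 0, nb_v[2], nv = 0;
      for (int i = 0; i < 3; ++i) {
        if (T.adj[u][i] != v) nb_u[nu++] = T.adj[u][i];
        if (T.adj[v][i] != u) nb_v[nv++] = T.adj[v][i];
      }
      for (int a = 0; a < 2; ++a) {
        int b = nb_u[1], c = nb_v[a];   // swap u's second neighbour with one of v's
        UTree T2 = T;
        T2.remove_edge(u, b);
        T2.remove_edge(v, c);
        T2.add_edge(u, c);
        T2.add_edge(v, b);
        long long s = score_full(T2, M);
        if (s < cur) { T = T2; cur = s; return true; }
      }
    }
    return false;
  }
  CompDP C1, C2;
  for (auto &e : edges) {
    int u = e.first, v = e.second;
    compute_attachments(T, M, u, v, C1);
    compute_attachments(T, M, v, u, C2);
    for (size_t i = 0; i < C1.atts.size(); ++i) {
      for (size_t j = 0; j < C2.atts.size(); ++j) {
        if ((int)i == C1.virtual_idx && (int)j == C2.virtual_idx) continue;
        if (swap_kind == 1 &&
            (int)i != C1.virtual_idx && (int)j != C2.virtual_idx) continue;
        long long s = pair_score(&C1.E[C1.atts[i].off], &C2.E[C2.atts[j].off], M);
        if (s < cur) {
          apply_tbr(T, u, v, C1.atts[i], C2.atts[j]);
          cur = s;
          return true;
        }
      }
    }
  }
  return false;
}

// Enumerate neighbours at exactly `target` score (for plateau harvesting),
// or report a strictly better tree if one is found.
static bool collect_equal_neighbors(const UTree &T, const CharMatrix &M,
                                    long long target, int swap_kind,
                                    std::vector<UTree> &out,
                                    UTree &better, long long &better_score) {
  std::vector<std::pair<int, int>> edges;
  list_edges(T, edges);
  if (swap_kind == 0) {
    for (auto &e : edges) {
      int u = e.first, v = e.second;
      if (u < T.m || v < T.m) continue;
      int nb_u[2], nu = 0, nb_v[2], nv = 0;
      for (int i = 0; i < 3; ++i) {
        if (T.adj[u][i] != v) nb_u[nu++] = T.adj[u][i];
        if (T.adj[v][i] != u) nb_v[nv++] = T.adj[v][i];
      }
      for (int a = 0; a < 2; ++a) {
        UTree T2 = T;
        T2.remove_edge(u, nb_u[1]);
        T2.remove_edge(v, nb_v[a]);
        T2.add_edge(u, nb_v[a]);
        T2.add_edge(v, nb_u[1]);
        long long s = score_full(T2, M);
        if (s < target) { better = T2; better_score = s; return true; }
        if (s == target) out.push_back(T2);
      }
    }
    return false;
  }
  CompDP C1, C2;
  for (auto &e : edges) {
    int u = e.first, v = e.second;
    compute_attachments(T, M, u, v, C1);
    compute_attachments(T, M, v, u, C2);
    for (size_t i = 0; i < C1.atts.size(); ++i) {
      for (size_t j = 0; j < C2.atts.size(); ++j) {
        if ((int)i == C1.virtual_idx && (int)j == C2.virtual_idx) continue;
        if (swap_kind == 1 &&
            (int)i != C1.virtual_idx && (int)j != C2.virtual_idx) continue;
        long long s = pair_score(&C1.E[C1.atts[i].off], &C2.E[C2.atts[j].off], M);
        if (s < target) {
          better = T;
          apply_tbr(better, u, v, C1.atts[i], C2.atts[j]);
          better_score = s;
          return true;
        }
        if (s == target) {
          UTree T2 = T;
          apply_tbr(T2, u, v, C1.atts[i], C2.atts[j]);
          out.push_back(T2);
        }
      }
    }
  }
  return false;
}

// ------------------------------------------------------------------
// Stepwise addition
// ------------------------------------------------------------------

static UTree stepwise_addition(const CharMatrix &M,
                               const std::vector<int> &order,
                               std::mt19937 &rng) {
  int m = M.m;
  UTree T(m);
  if (m == 2) {
    T.add_edge(order[0], order[1]);
    return T;
  }
  int x = T.next_internal++;
  T.add_edge(x, order[0]);
  T.add_edge(x, order[1]);
  T.add_edge(x, order[2]);
  CompDP C;
  std::vector<int> leafE;
  for (size_t idx = 3; idx < order.size(); ++idx) {
    int tip = order[idx];
    int anchor = order[0];
    compute_attachments(T, M, anchor, -1, C);
    leafE.assign(2 * M.k, 0);
    for (int c = 0; c < M.k; ++c) {
      uint8_t msk = M.at(tip, c);
      leafE[2 * c] = (msk & 1) ? 0 : BIGC;
      leafE[2 * c + 1] = (msk & 2) ? 0 : BIGC;
    }
    long long best = -1;
    std::vector<int> best_atts;
    for (size_t i = 0; i < C.atts.size(); ++i) {
      long long s = pair_score(&leafE[0], &C.E[C.atts[i].off], M);
      if (best < 0 || s < best) { best = s; best_atts.clear(); }
      if (s == best) best_atts.push_back((int)i);
    }
    int pick = best_atts[rng() % best_atts.size()];
    const Att &A = C.atts[pick];
    if (A.kind == 2) {
      // two-tip tree grows via a fresh internal node
      int w = T.next_internal++;
      int other = T.adj[A.p][0];
      T.remove_edge(A.p, other);
      T.add_edge(A.p, w);
      T.add_edge(w, other);
      T.add_edge(w, tip);
    } else {
      insert_tip(T, tip, A.p, A.c);
    }
  }
  return T;
}

// ------------------------------------------------------------------
// Exported: score a rooted (possibly multifurcating) tree
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fitch_rooted(IntegerMatrix edge, int ntip, IntegerMatrix states,
                      NumericVector weights) {
  int k = states.ncol();
  int nE = edge.nrow();
  int maxnode = ntip;
  for (int i = 0; i < nE; ++i) {
    maxnode = std::max(maxnode, edge(i, 0));
    maxnode = std::max(maxnode, edge(i, 1));
  }
  std::vector<std::vector<int>> kids(maxnode + 1);
  std::vector<char> is_child(maxnode + 1, 0);
  for (int i = 0; i < nE; ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    is_child[edge(i, 1)] = 1;
  }
  int root = -1;
  for (int i = 0; i < nE; ++i)
    if (!is_child[edge(i, 0)]) { root = edge(i, 0); break; }
  // postorder via preorder reversal
  std::vector<int> pre;
  pre.push_back(root);
  for (size_t qi = 0; qi < pre.size(); ++qi)
    for (int c : kids[pre[qi]]) pre.push_back(c);
  std::vector<int> C((size_t)(maxnode + 1) * 2 * k, 0);
  for (int qi = (int)pre.size() - 1; qi >= 0; --qi) {
    int nd = pre[qi];
    int *cn = &C[(size_t)nd * 2 * k];
    if (nd <= ntip) {
      for (int c = 0; c < k; ++c) {
        int msk = states(nd - 1, c);
        cn[2 * c] = (msk & 1) ? 0 : BIGC;
        cn[2 * c + 1] = (msk & 2) ? 0 : BIGC;
      }
    } else {
      for (int ch : kids[nd]) {
        const int *cc = &C[(size_t)ch * 2 * k];
        for (int c = 0; c < k; ++c) {
          int a = cc[2 * c], b = cc[2 * c + 1];
          cn[2 * c] += std::min(a, b + 1);
          cn[2 * c + 1] += std::min(b, a + 1);
        }
      }
    }
  }
  IntegerVector steps(k);
  long double tot = 0;
  const int *cr = &C[(size_t)root * 2 * k];
  for (int c = 0; c < k; ++c) {
    steps[c] = std::min(cr[2 * c], cr[2 * c + 1]);
    tot += (long double)weights[c] * steps[c];
  }
  return List::create(_["total"] = (double)tot, _["steps"] = steps);
}

// ------------------------------------------------------------------
// Exported: heuristic search
// ------------------------------------------------------------------

static CharMatrix build_matrix(const IntegerMatrix &states,
                               const NumericVector &weights) {
  CharMatrix M;
  M.m = states.nrow();
  M.k = states.ncol();
  M.st.resize((size_t)M.m * M.k);
  for (int i = 0; i < M.m; ++i)
    for (int c = 0; c < M.k; ++c)
      M.st[(size_t)i * M.k + c] = (uint8_t)states(i, c);
  M.w.resize(M.k);
  for (int c = 0; c < M.k; ++c) M.w[c] = (long long)std::llround(weights[c]);
  return M;
}

// [[Rcpp::export]]
List cpp_heuristic_search(IntegerMatrix states, NumericVector weights,
                          CharacterVector taxa, int outgroup,
                          int n_reps, std::string swap, int max_trees,
                          int seed, double lower_bound) {
  CharMatrix M = build_matrix(states, weights);
  int m = M.m;
  std::vector<std::string> labels(m);
  for (int i = 0; i < m; ++i) labels[i] = as<std::string>(taxa[i]);
  int swap_kind = (swap == "NNI") ? 0 : (swap == "SPR") ? 1 : 2;
  long long lb = (long long)std::llround(lower_bound);

  long long best = -1;
  std::vector<UTree> best_trees;
  std::set<std::string> seen;
  int reps_done = 0;

  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;

  for (int rep = 0; rep < n_reps; ++rep) {
    Rcpp::checkUserInterrupt();
    std::mt19937 rng((uint32_t)(1000003ULL * (uint64_t)(uint32_t)seed + rep));
    std::shuffle(order.begin(), order.end(), rng);
    UTree T = stepwise_addition(M, order, rng);
    long long cur = score_full(T, M);
    if (cur > lb && m >= 4) {
      while (swap_sweep_improve(T, M, cur, swap_kind)) {
        if (cur <= lb) break;
      }
    }
    ++reps_done;
    if (best < 0 || cur < best) {
      best = cur;
      best_trees.clear();
      seen.clear();
    }
    if (cur == best) {
      std::string key = rooted_newick(T, outgroup, labels);
      if (seen.insert(key).second) best_trees.push_back(T);
    }
  }

  // plateau harvesting: close the best set under equal-score swaps
  bool hit_max = false;
  if (m >= 4) {
    std::deque<size_t> queue;
    for (size_t i = 0; i < best_trees.size(); ++i) queue.push_back(i);
    while (!queue.empty()) {
      Rcpp::checkUserInterrupt();
      if ((int)best_trees.size() >= max_trees) { hit_max = true; break; }
      size_t idx = queue.front();
      queue.pop_front();
      UTree cur_tree = best_trees[idx];
      std::vector<UTree> eq;
      UTree better(m);
      long long better_score = 0;
      bool found_better = collect_equal_neighbors(cur_tree, M, best, swap_kind,
                                                  eq, better, better_score);
      if (found_better) {
        long long cur = better_score;
        while (swap_sweep_improve(better, M, cur, swap_kind)) {
          if (cur <= lb) break;
        }
        best = cur;
        best_trees.clear();
        seen.clear();
        queue.clear();
        std::string key = rooted_newick(better, outgroup, labels);
        seen.insert(key);
        best_trees.push_back(better);
        queue.push_back(0);
        continue;
      }
      for (auto &T2 : eq) {
        if ((int)best_trees.size() >= max_trees) { hit_max = true; break; }
        std::string key = rooted_newick(T2, outgroup, labels);
        if (seen.insert(key).second) {
          best_trees.push_back(T2);
          queue.push_back(best_trees.size() - 1);
        }
      }
      if (hit_max) break;
    }
  }

  CharacterVector out(best_trees.size());
  for (size_t i = 0; i < best_trees.size(); ++i)
    out[i] = rooted_newick(best_trees[i], outgroup, labels);
  return List::create(_["score"] = (double)best, _["trees"] = out,
                      _["reps_completed"] = reps_done,
                      _["hit_max_trees"] = hit_max);
}

// ------------------------------------------------------------------
// Exported: exhaustive branch-and-bound search
// ------------------------------------------------------------------

struct ExhaustState {
  const CharMatrix *M;
  int outgroup;
  const std::vector<std::string> *labels;
  long long best;
  std::set<std::string> trees;
  long long n_scored;
};

static void exhaust_rec(UTree &T, int next_idx, ExhaustState &S) {
  const CharMatrix &M = *S.M;
  int m = M.m;
  if (next_idx == m) {
    long long s = score_full(T, M);
    ++S.n_scored;
    if (S.best < 0 || s < S.best) {
      S.best = s;
      S.trees.clear();
    }
    if (s == S.best) S.trees.insert(rooted_newick(T, S.outgroup, *S.labels));
    return;
  }
  std::vector<std::pair<int, int>> edges;
  list_edges(T, edges);
  for (auto &e : edges) {
    insert_tip(T, next_idx, e.first, e.second);
    long long s = score_full(T, M);
    ++S.n_scored;
    if (S.best < 0 || s <= S.best) exhaust_rec(T, next_idx + 1, S);
    remove_last_tip(T, next_idx);
  }
}

// [[Rcpp::export]]
List cpp_exhaustive_search(IntegerMatrix states, NumericVector weights,
                           CharacterVector taxa, int outgroup) {
  CharMatrix M = build_matrix(states, weights);
  int m = M.m;
  std::vector<std::string> labels(m);
  for (int i = 0; i < m; ++i) labels[i] = as<std::string>(taxa[i]);
  ExhaustState S{&M, outgroup, &labels, -1, {}, 0};
  UTree T(m);
  if (m < 3) stop("exhaustive search needs at least 3 taxa");
  int x = T.next_internal++;
  T.add_edge(x, 0);
  T.add_edge(x, 1);
  T.add_edge(x, 2);
  exhaust_rec(T, 3, S);
  CharacterVector out(S.trees.size());
  int i = 0;
  for (auto &s : S.trees) out[i++] = s;
  return List::create(_["score"] = (double)S.best, _["trees"] = out,
                      _["n_scored"] = (double)S.n_scored);
}
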