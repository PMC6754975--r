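// Core parsimony machinery: Fitch-Hartigan scoring, stepwise addition,
// TBR branch swapping and exhaustive enumeration over unrooted binary trees.
// Trees cross the R boundary as ape-style edge matrices (1-based ids, tips
// 1..ntip); internally the search operates on flat adjacency arrays over
// 0-based node ids (degree <= 3: unrooted binary trees). General rooted
// trees with polytomies are handled by the standalone scorer and key/root
// helpers at the bottom. Leaf sets are limited to 64 taxa (splits are packed
// into uint64_t).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <functional>
#include <set>
#include <sstream>
#include <vector>

using namespace Rcpp;

namespace {

// ---------- fast unrooted-binary representation for the search ----------

struct FTree {
  int ntip;
  std::vector<std::array<int, 3>> nb;
  std::vector<uint8_t> deg;
  FTree(int ntip_, int nnodes) : ntip(ntip_), nb(nnodes), deg(nnodes, 0) {}
};

inline void add_edge(FTree& t, int u, int v) {
  t.nb[u][t.deg[u]++] = v;
  t.nb[v][t.deg[v]++] = u;
}

inline void drop_nb(FTree& t, int u, int v) {
  for (int i = 0; i < t.deg[u]; ++i)
    if (t.nb[u][i] == v) {
      t.nb[u][i] = t.nb[u][--t.deg[u]];
      return;
    }
}

inline void remove_edge(FTree& t, int u, int v) {
  drop_nb(t, u, v);
  drop_nb(t, v, u);
}

struct Workspace {
  std::vector<int> order, parent, stk;
  std::vector<uint32_t> S;
  std::vector<uint64_t> below;
};

// preorder from `root` with virtual parent `rootParent`
void preorder_f(const FTree& t, int root, int rootParent, Workspace& ws) {
  ws.order.clear();
  ws.parent.assign(t.nb.size(), -2);
  ws.stk.clear();
  ws.stk.push_back(root);
  ws.parent[root] = rootParent;
  while (!ws.stk.empty()) {
    int u = ws.stk.back();
    ws.stk.pop_back();
    ws.order.push_back(u);
    for (int i = 0; i < t.deg[u]; ++i) {
      int v = t.nb[u][i];
      if (v != ws.parent[u]) {
        ws.parent[v] = u;
        ws.stk.push_back(v);
      }
    }
  }
}

// Fitch length rooted on the pendant edge of `roottip`; every internal node
// then has exactly two traversal children. Early abort past `bound` (>=0).
long score_ftree(const FTree& t, int roottip, const int* masks, int nrow,
                 int nchar, long bound, Workspace& ws) {
  int root = t.nb[roottip][0];
  preorder_f(t, root, roottip, ws);
  ws.S.resize(t.nb.size() * nchar);
  long total = 0;
  for (size_t oi = ws.order.size(); oi-- > 0;) {
    int u = ws.order[oi];
    uint32_t* Su = &ws.S[(size_t)u * nchar];
    if (u < t.ntip) {
      for (int c = 0; c < nchar; ++c) Su[c] = (uint32_t)masks[u + (size_t)nrow * c];
      continue;
    }
    int ch[2], nch = 0;
    for (int i = 0; i < t.deg[u]; ++i)
      if (t.nb[u][i] != ws.parent[u]) ch[nch++] = t.nb[u][i];
    const uint32_t* A = &ws.S[(size_t)ch[0] * nchar];
    const uint32_t* B = &ws.S[(size_t)ch[1] * nchar];
    for (int c = 0; c < nchar; ++c) {
      uint32_t in = A[c] & B[c];
      if (in) {
        Su[c] = in;
      } else {
        Su[c] = A[c] | B[c];
        ++total;
      }
    }
    if (bound >= 0 && total > bound) return total;
  }
  const uint32_t* Sr = &ws.S[(size_t)root * nchar];
  for (int c = 0; c < nchar; ++c)
    if (!(Sr[c] & (uint32_t)masks[roottip + (size_t)nrow * c])) ++total;
  return total;
}

int lowest_tip_f(const FTree& t) {
  for (int i = 0; i < t.ntip; ++i)
    if (t.deg[i]) return i;
  stop("tree has no attached tips");
}

// canonical split-set key (sorted tip sets on the side away from the root tip)
std::vector<uint64_t> key_ftree(const FTree& t, Workspace& ws) {
  int rtip = lowest_tip_f(t);
  int root = t.nb[rtip][0];
  preorder_f(t, root, rtip, ws);
  ws.below.assign(t.nb.size(), 0);
  int present = 0;
  for (int i = 0; i < t.ntip; ++i)
    if (t.deg[i]) ++present;
  for (size_t oi = ws.order.size(); oi-- > 0;) {
    int u = ws.order[oi];
    if (u < t.ntip) {
      ws.below[u] = 1ULL << u;
    } else {
      uint64_t b = 0;
      for (int i = 0; i < t.deg[u]; ++i)
        if (t.nb[u][i] != ws.parent[u]) b |= ws.below[t.nb[u][i]];
      ws.below[u] = b;
    }
  }
  std::vector<uint64_t> key;
  key.reserve(t.ntip);
  for (int u : ws.order) {
    if (u == root) continue;
    int pc = __builtin_popcountll(ws.below[u]);
    if (pc >= 2 && pc <= present - 2) key.push_back(ws.below[u]);
  }
  std::sort(key.begin(), key.end());
  return key;
}

// Enumerate every TBR reconnection product of an unrooted binary tree:
// bisection at every branch, reconnection at every branch pair of the two
// fragments; the combination recreating the original topology is skipped.
// The tree passed to `visit` is a temporarily modified working copy; visit
// must copy it to keep it, and returns true to stop the enumeration.
template <typename F>
void for_each_tbr(const FTree& t0, F&& visit) {
  std::vector<std::pair<int, int>> edges;
  for (int u = 0; u < (int)t0.nb.size(); ++u)
    for (int i = 0; i < t0.deg[u]; ++i)
      if (u < t0.nb[u][i]) edges.push_back({u, t0.nb[u][i]});
  std::vector<std::pair<int, int>> eA, eB;
  for (auto& e : edges) {
    int u = e.first, v = e.second;
    FTree W = t0;
    remove_edge(W, u, v);
    auto suppress = [&W](int a, std::pair<int, int>& restored) -> bool {
      if (W.deg[a] == 2) {
        int p = W.nb[a][0], q = W.nb[a][1];
        remove_edge(W, a, p);
        remove_edge(W, a, q);
        add_edge(W, p, q);
        restored = {std::min(p, q), std::max(p, q)};
        return true;
      }
      return false;  // a detached tip is its own attachment point
    };
    std::pair<int, int> restA{-1, -1}, restB{-1, -1};
    bool supA = suppress(u, restA);
    bool supB = suppress(v, restB);
    // split remaining edges by component
    std::vector<int8_t> inA(W.nb.size(), 0);
    {
      std::vector<int> st{supA ? restA.first : u};
      inA[st[0]] = 1;
      while (!st.empty()) {
        int x = st.back();
        st.pop_back();
        for (int i = 0; i < W.deg[x]; ++i) {
          int y = W.nb[x][i];
          if (!inA[y]) {
            inA[y] = 1;
            st.push_back(y);
          }
        }
      }
    }
    eA.clear();
    eB.clear();
    for (int x = 0; x < (int)W.nb.size(); ++x)
      for (int i = 0; i < W.deg[x]; ++i) {
        int y = W.nb[x][i];
        if (x < y) (inA[x] ? eA : eB).push_back({x, y});
      }
    if (!supA) eA.push_back({u, -1});
    if (!supB) eB.push_back({v, -1});
    bool stopall = false;
    for (auto& ea : eA) {
      int na;
      if (ea.second < 0) {
        na = ea.first;
      } else {
        remove_edge(W, ea.first, ea.second);
        add_edge(W, u, ea.first);
        add_edge(W, u, ea.second);
        na = u;
      }
      bool origA = supA ? (ea == restA) : true;
      for (auto& eb : eB) {
        bool origB = supB ? (eb == restB) : true;
        if (origA && origB) continue;
        int nbn;
        if (eb.second < 0) {
          nbn = eb.first;
        } else {
          remove_edge(W, eb.first, eb.second);
          add_edge(W, v, eb.first);
          add_edge(W, v, eb.second);
          nbn = v;
        }
        add_edge(W, na, nbn);
        stopall = visit(W);
        remove_edge(W, na, nbn);
        if (eb.second >= 0) {
          remove_edge(W, v, eb.first);
          remove_edge(W, v, eb.second);
          add_edge(W, eb.first, eb.second);
        }
        if (stopall) break;
      }
      if (ea.second >= 0) {
        remove_edge(W, u, ea.first);
        remove_edge(W, u, ea.second);
        add_edge(W, ea.first, ea.second);
      }
      if (stopall) break;
    }
    if (stopall) return;
  }
}

// ---------- fused TBR sweep ----------
//
// For one bisection the two fragments are summarized by, per reconnection
// branch, the Fitch state set obtained when the fragment is rooted on that
// branch, plus the fragment's (rooting-invariant) parsimony length T. A
// reconnection pair (eA, eB) then scores
//   T_A + T_B + sum_c [ S_A,c(eA) & S_B,c(eB) == 0 ]
// which lets a full TBR neighborhood be evaluated in O(#pairs * nchar)
// instead of rescoring every neighbor tree from scratch.

struct FragData {
  long T = 0;
  std::vector<std::pair<int, int>> edges;  // (tip,-1) for a lone-tip fragment
  std::vector<uint32_t> S;                 // edges.size() x nchar
};

inline void fitch_combine(const uint32_t* a, const uint32_t* b, uint32_t* out,
                          int nchar, long* steps) {
  for (int c = 0; c < nchar; ++c) {
    uint32_t in = a[c] & b[c];
    if (in) {
      out[c] = in;
    } else {
      out[c] = a[c] | b[c];
      if (steps) ++*steps;
    }
  }
}

// Build reconnection-edge summaries for the fragment of W containing `seed`.
void build_frag(const FTree& W, int seed, const int* masks, int nrow, int nchar,
                FragData& out, Workspace& ws, std::vector<uint32_t>& down,
                std::vector<uint32_t>& up) {
  out.T = 0;
  out.edges.clear();
  if (W.deg[seed] == 0) {  // lone tip
    out.edges.push_back({seed, -1});
    out.S.assign(nchar, 0);
    for (int c = 0; c < nchar; ++c) out.S[c] = (uint32_t)masks[seed + (size_t)nrow * c];
    return;
  }
  // anchor at the lowest tip of the component
  preorder_f(W, seed, -1, ws);
  int anchor = -1;
  for (int u : ws.order)
    if (u < W.ntip && (anchor < 0 || u < anchor)) anchor = u;
  preorder_f(W, anchor, -1, ws);
  size_t nn = W.nb.size();
  down.resize(nn * nchar);
  up.resize(nn * nchar);
  // postorder: down sets
  for (size_t oi = ws.order.size(); oi-- > 0;) {
    int u = ws.order[oi];
    uint32_t* Du = &down[(size_t)u * nchar];
    if (u < W.ntip) {
      for (int c = 0; c < nchar; ++c) Du[c] = (uint32_t)masks[u + (size_t)nrow * c];
      continue;
    }
    int ch[2], nch = 0;
    for (int i = 0; i < W.deg[u]; ++i)
      if (W.nb[u][i] != ws.parent[u]) ch[nch++] = W.nb[u][i];
    fitch_combine(&down[(size_t)ch[0] * nchar], &down[(size_t)ch[1] * nchar],
                  Du, nchar, &out.T);
  }
  // close against the anchor leaf (root = anchor, single child rr)
  int rr = W.nb[anchor][0];
  {
    const uint32_t* Dr = &down[(size_t)rr * nchar];
    for (int c = 0; c < nchar; ++c)
      if (!(Dr[c] & (uint32_t)masks[anchor + (size_t)nrow * c])) ++out.T;
  }
  // preorder: up sets (up[c] = state set of the component on the parent side)
  for (int u : ws.order) {
    if (u == anchor) continue;
    if (ws.parent[u] == anchor) {
      uint32_t* Uu = &up[(size_t)u * nchar];
      for (int c = 0; c < nchar; ++c) Uu[c] = (uint32_t)masks[anchor + (size_t)nrow * c];
      continue;
    }
    int p = ws.parent[u];
    int sib = -1;
    for (int i = 0; i < W.deg[p]; ++i) {
      int v = W.nb[p][i];
      if (v != u && v != ws.parent[p]) sib = v;
    }
    fitch_combine(&up[(size_t)p * nchar], &down[(size_t)sib * nchar],
                  &up[(size_t)u * nchar], nchar, nullptr);
  }
  // per-edge root-on-edge sets
  out.edges.reserve(ws.order.size());
  size_t ne = 0;
  out.S.resize((ws.order.size() - 1) * nchar);
  for (int u : ws.order) {
    if (u == anchor) continue;
    out.edges.push_back({ws.parent[u], u});
    fitch_combine(&down[(size_t)u * nchar], &up[(size_t)u * nchar],
                  &out.S[ne * nchar], nchar, nullptr);
    ++ne;
  }
}

struct TbrMove {
  int cu, cv;               // cut edge
  std::pair<int, int> ea, eb;  // reconnection edges ((tip,-1) = lone tip)
};

// Apply a TBR move to a copy of `t0` and return the rearranged tree.
FTree apply_tbr(const FTree& t0, const TbrMove& mv) {
  FTree X = t0;
  remove_edge(X, mv.cu, mv.cv);
  auto suppress = [&X](int a) {
    if (X.deg[a] == 2) {
      int p = X.nb[a][0], q = X.nb[a][1];
      remove_edge(X, a, p);
      remove_edge(X, a, q);
      add_edge(X, p, q);
    }
  };
  suppress(mv.cu);
  suppress(mv.cv);
  int na = mv.cu, nbn = mv.cv;
  if (mv.ea.second < 0) {
    na = mv.ea.first;
  } else {
    remove_edge(X, mv.ea.first, mv.ea.second);
    add_edge(X, mv.cu, mv.ea.first);
    add_edge(X, mv.cu, mv.ea.second);
  }
  if (mv.eb.second < 0) {
    nbn = mv.eb.first;
  } else {
    remove_edge(X, mv.eb.first, mv.eb.second);
    add_edge(X, mv.cv, mv.eb.first);
    add_edge(X, mv.cv, mv.eb.second);
  }
  add_edge(X, na, nbn);
  return X;
}

inline bool same_edge(const std::pair<int, int>& a, int p, int q) {
  return (a.first == p && a.second == q) || (a.first == q && a.second == p);
}

// One full TBR sweep of `cur` using the fused evaluator. On finding a pair
// scoring below `curlen` the move is applied immediately (first improvement)
// and the function returns true. Otherwise all pairs scoring exactly
// `curlen` are collected (deduplicated, up to `cap`) and false is returned.
bool tbr_sweep(FTree& cur, long& curlen, const int* masks, int nrow, int nchar,
               std::vector<FTree>& equals, int cap, Workspace& ws,
               long* nscored) {
  std::vector<std::pair<int, int>> edges;
  for (int u = 0; u < (int)cur.nb.size(); ++u)
    for (int i = 0; i < cur.deg[u]; ++i)
      if (u < cur.nb[u][i]) edges.push_back({u, cur.nb[u][i]});
  equals.clear();
  std::set<std::vector<uint64_t>> eqseen;
  static FragData fa, fb;
  static std::vector<uint32_t> bufd, bufu;
  for (auto& e : edges) {
    int u = e.first, v = e.second;
    FTree W = cur;
    remove_edge(W, u, v);
    std::pair<int, int> restA{-1, -1}, restB{-1, -1};
    auto suppress = [&W](int a, std::pair<int, int>& restored) {
      if (W.deg[a] == 2) {
        int p = W.nb[a][0], q = W.nb[a][1];
        remove_edge(W, a, p);
        remove_edge(W, a, q);
        add_edge(W, p, q);
        restored = {p, q};
      }
    };
    suppress(u, restA);
    suppress(v, restB);
    int seedA = restA.first >= 0 ? restA.first : u;
    int seedB = restB.first >= 0 ? restB.first : v;
    build_frag(W, seedA, masks, nrow, nchar, fa, ws, bufd, bufu);
    build_frag(W, seedB, masks, nrow, nchar, fb, ws, bufd, bufu);
    long Tab = fa.T + fb.T;
    for (size_t ia = 0; ia < fa.edges.size(); ++ia) {
      bool origA = restA.first < 0 ||
                   same_edge(fa.edges[ia], restA.first, restA.second);
      const uint32_t* SA = &fa.S[ia * nchar];
      for (size_t ib = 0; ib < fb.edges.size(); ++ib) {
        if (origA && (restB.first < 0 ||
                      same_edge(fb.edges[ib], restB.first, restB.second)))
          continue;
        const uint32_t* SB = &fb.S[ib * nchar];
        long L = Tab;
        for (int c = 0; c < nchar; ++c)
          if (!(SA[c] & SB[c])) ++L;
        if (nscored) ++*nscored;
        TbrMove mv{u, v, fa.edges[ia], fb.edges[ib]};
        if (L < curlen) {
          cur = apply_tbr(cur, mv);
          curlen = L;
          return true;
        }
        if (L == curlen && (int)equals.size() < cap) {
          FTree X = apply_tbr(cur, mv);
          if (eqseen.insert(key_ftree(X, ws)).second) equals.push_back(std::move(X));
        }
      }
    }
  }
  return false;
}

// ---------- conversions between FTree and ape edge matrices ----------

FTree ftree_from_edge(const IntegerMatrix& edge, int ntip) {
  int mx = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
  FTree t(ntip, mx);
  for (int i = 0; i < edge.nrow(); ++i) add_edge(t, edge(i, 0) - 1, edge(i, 1) - 1);
  for (auto d : t.deg)
    if (d > 3) stop("tree is not binary (a node has degree > 3)");
  // suppress one degree-2 node (rooted input) to get the unrooted tree
  for (int u = ntip; u < (int)t.nb.size(); ++u)
    if (t.deg[u] == 2) {
      int p = t.nb[u][0], q = t.nb[u][1];
      remove_edge(t, u, p);
      remove_edge(t, u, q);
      add_edge(t, p, q);
      break;
    }
  return t;
}

IntegerMatrix ftree_to_edge(const FTree& t, Workspace& ws) {
  int rtip = lowest_tip_f(t);
  int root = t.nb[rtip][0];
  preorder_f(t, root, -1, ws);
  int nedge = (int)ws.order.size() - 1;
  IntegerMatrix edge(nedge, 2);
  std::vector<int> newid(t.nb.size(), 0);
  int nexti = t.ntip + 1;
  for (int u : ws.order) newid[u] = (u < t.ntip) ? (u + 1) : nexti++;
  int r = 0;
  for (int u : ws.order) {
    if (u == root) continue;
    edge(r, 0) = newid[ws.parent[u]];
    edge(r, 1) = newid[u];
    ++r;
  }
  return edge;
}

}  // namespace

// ---------- exported search operations ----------

// [[Rcpp::export]]
List cpp_stepwise_addition(IntegerMatrix masks, IntegerVector order0, int hold) {
  int ntip = masks.nrow(), nchar = masks.ncol();
  int m = order0.size();
  if (m < 3) stop("need at least 3 taxa");
  Workspace ws;
  int nnodes = ntip + m - 2;
  std::vector<FTree> held;
  {
    FTree t(ntip, nnodes);
    add_edge(t, order0[0], ntip);
    add_edge(t, order0[1], ntip);
    add_edge(t, order0[2], ntip);
    held.push_back(t);
  }
  int roottip = order0[0];
  struct Cand {
    long score;
    int h, eu, ev;
  };
  std::vector<Cand> cand;
  for (int i = 3; i < m; ++i) {
    int tip = order0[i];
    int newint = ntip + i - 2;
    cand.clear();
    for (int hi = 0; hi < (int)held.size(); ++hi) {
      FTree& h = held[hi];
      std::vector<std::pair<int, int>> edges;
      for (int u = 0; u < (int)h.nb.size(); ++u)
        for (int k = 0; k < h.deg[u]; ++k)
          if (u < h.nb[u][k]) edges.push_back({u, h.nb[u][k]});
      for (auto& e : edges) {
        remove_edge(h, e.first, e.second);
        add_edge(h, e.first, newint);
        add_edge(h, e.second, newint);
        add_edge(h, newint, tip);
        long s = score_ftree(h, roottip, &masks[0], ntip, nchar, -1, ws);
        cand.push_back({s, hi, e.first, e.second});
        remove_edge(h, newint, tip);
        remove_edge(h, e.first, newint);
        remove_edge(h, e.second, newint);
        add_edge(h, e.first, e.second);
      }
    }
    std::stable_sort(cand.begin(), cand.end(),
                     [](const Cand& a, const Cand& b) { return a.score < b.score; });
    std::vector<FTree> nxt;
    std::set<std::vector<uint64_t>> seen;
    for (auto& c : cand) {
      if ((int)nxt.size() >= hold) break;
      FTree x = held[c.h];
      remove_edge(x, c.eu, c.ev);
      add_edge(x, c.eu, newint);
      add_edge(x, c.ev, newint);
      add_edge(x, newint, tip);
      if (seen.insert(key_ftree(x, ws)).second) nxt.push_back(std::move(x));
    }
    held.swap(nxt);
    Rcpp::checkUserInterrupt();
  }
  List trees;
  IntegerVector lens;
  for (auto& h : held) {
    trees.push_back(ftree_to_edge(h, ws));
    lens.push_back((int)score_ftree(h, roottip, &masks[0], ntip, nchar, -1, ws));
  }
  return List::create(_["edges"] = trees, _["lengths"] = lens);
}

// [[Rcpp::export]]
List cpp_tbr_neighbors(IntegerMatrix edge, int ntip) {
  FTree t = ftree_from_edge(edge, ntip);
  Workspace ws;
  std::set<std::vector<uint64_t>> seen{key_ftree(t, ws)};
  List out;
  for_each_tbr(t, [&](FTree& X) {
    if (seen.insert(key_ftree(X, ws)).second) out.push_back(ftree_to_edge(X, ws));
    return false;
  });
  return out;
}

// Branch swapping of a pool of start trees. Each distinct start is swapped:
// a first-improvement TBR descent to a local optimum, followed by collection
// of the equal-length TBR closure whenever the local optimum ties the best
// length seen so far. Trees discovered at the best length join the queue and
// are swapped in turn, so the result is closed under equal-or-better TBR
// moves from every start (bounded by maxTrees).
// [[Rcpp::export]]
List cpp_tbr_search(List startEdges, int ntip, IntegerMatrix masks, int maxTrees) {
  int nchar = masks.ncol();
  Workspace ws;
  std::vector<FTree> queue;
  std::set<std::vector<uint64_t>> queued;
  for (int i = 0; i < startEdges.size(); ++i) {
    FTree t = ftree_from_edge(startEdges[i], ntip);
    if (queued.insert(key_ftree(t, ws)).second) queue.push_back(std::move(t));
  }
  if (queue.empty()) stop("no start trees");
  long best = LONG_MAX;
  for (auto& t : queue)
    best = std::min(best, score_ftree(t, 0, &masks[0], ntip, nchar, -1, ws));
  bool truncated = false;
  long nscored = 0;
  size_t qi = 0;
  std::vector<FTree> equals;
  while (qi < queue.size()) {
    FTree cur = queue[qi];
    long curlen = score_ftree(cur, 0, &masks[0], ntip, nchar, -1, ws);
    // first-improvement descent to a TBR local optimum; the final
    // (non-improving) sweep doubles as the equal-length neighbor collection
    while (tbr_sweep(cur, curlen, &masks[0], ntip, nchar, equals, maxTrees, ws,
                     &nscored)) {
      Rcpp::checkUserInterrupt();
    }
    if (curlen < best) best = curlen;
    if (curlen == best) {
      equals.push_back(cur);
      for (auto& t : equals) {
        auto k = key_ftree(t, ws);
        if (!queued.count(k)) {
          if ((int)queue.size() < maxTrees) {
            queued.insert(k);
            queue.push_back(std::move(t));
          } else {
            truncated = true;
          }
        }
      }
    }
    ++qi;
    Rcpp::checkUserInterrupt();
  }
  List trees;
  for (auto& t : queue) {
    long L = score_ftree(t, 0, &masks[0], ntip, nchar, -1, ws);
    if (L == best) trees.push_back(ftree_to_edge(t, ws));
  }
  return List::create(_["best_length"] = (double)best, _["edges"] = trees,
                      _["truncated"] = truncated, _["n_scored"] = (double)nscored);
}

// [[Rcpp::export]]
List cpp_exhaustive_search(IntegerMatrix masks, int maxTrees) {
  int ntip = masks.nrow(), nchar = masks.ncol();
  if (ntip < 4 || ntip > 9) stop("exhaustive search supports 4..9 taxa");
  Workspace ws;
  int nnodes = 2 * ntip - 2;
  FTree t(ntip, nnodes);
  add_edge(t, 0, ntip);
  add_edge(t, 1, ntip);
  add_edge(t, 2, ntip);
  long best = LONG_MAX, counted = 0;
  bool truncated = false;
  std::vector<FTree> bestTrees;
  std::function<void(int)> rec = [&](int nextTip) {
    if (nextTip == ntip) {
      long L = score_ftree(t, 0, &masks[0], ntip, nchar, best, ws);
      ++counted;
      if (L < best) {
        best = L;
        bestTrees.clear();
        truncated = false;
      }
      if (L == best) {
        if ((int)bestTrees.size() < maxTrees)
          bestTrees.push_back(t);
        else
          truncated = true;
      }
      return;
    }
    std::vector<std::pair<int, int>> edges;
    for (int u = 0; u < (int)t.nb.size(); ++u)
      for (int i = 0; i < t.deg[u]; ++i)
        if (u < t.nb[u][i]) edges.push_back({u, t.nb[u][i]});
    int w = ntip + nextTip - 2;
    for (auto& e : edges) {
      remove_edge(t, e.first, e.second);
      add_edge(t, e.first, w);
      add_edge(t, e.second, w);
      add_edge(t, w, nextTip);
      rec(nextTip + 1);
      remove_edge(t, w, nextTip);
      remove_edge(t, e.first, w);
      remove_edge(t, e.second, w);
      add_edge(t, e.first, e.second);
    }
    Rcpp::checkUserInterrupt();
  };
  rec(3);
  List trees;
  for (auto& b : bestTrees) trees.push_back(ftree_to_edge(b, ws));
  return List::create(_["best_length"] = (double)best, _["edges"] = trees,
                      _["n_topologies"] = (double)counted, _["truncated"] = truncated);
}

// ---------- general rooted-tree helpers (polytomies allowed) ----------

namespace {

struct GTree {
  int ntip;
  std::vector<std::vector<int>> adj;
};

GTree gtree_from_edge(const IntegerMatrix& edge, int ntip) {
  int mx = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
  GTree t;
  t.ntip = ntip;
  t.adj.resize(mx);
  for (int i = 0; i < edge.nrow(); ++i) {
    int u = edge(i, 0) - 1, v = edge(i, 1) - 1;
    t.adj[u].push_back(v);
    t.adj[v].push_back(u);
  }
  return t;
}

void preorder_g(const GTree& t, int root, int rootParent,
                std::vector<int>& order, std::vector<int>& parent) {
  order.clear();
  parent.assign(t.adj.size(), -2);
  std::vector<int> stk{root};
  parent[root] = rootParent;
  while (!stk.empty()) {
    int u = stk.back();
    stk.pop_back();
    order.push_back(u);
    for (int v : t.adj[u])
      if (v != parent[u]) {
        parent[v] = u;
        stk.push_back(v);
      }
  }
}

}  // namespace

// Per-character parsimony steps of a rooted tree (root = phylo node ntip+1),
// exact on polytomies via the Hartigan counting rule.
// [[Rcpp::export]]
IntegerVector cpp_fitch_counts(IntegerMatrix edge, int ntip, IntegerMatrix masks) {
  GTree t = gtree_from_edge(edge, ntip);
  int nchar = masks.ncol();
  std::vector<int> order, parent;
  preorder_g(t, ntip, -1, order, parent);
  std::vector<uint32_t> S(t.adj.size() * nchar);
  IntegerVector out(nchar);
  for (size_t oi = order.size(); oi-- > 0;) {
    int u = order[oi];
    uint32_t* Su = &S[(size_t)u * nchar];
    if (u < ntip) {
      for (int c = 0; c < nchar; ++c) Su[c] = (uint32_t)masks(u, c);
      continue;
    }
    std::vector<int> ch;
    for (int v : t.adj[u])
      if (v != parent[u]) ch.push_back(v);
    for (int c = 0; c < nchar; ++c) {
      int cnt[32] = {0};
      uint32_t un = 0;
      for (int k : ch) {
        uint32_t m = S[(size_t)k * nchar + c];
        un |= m;
        while (m) {
          ++cnt[__builtin_ctz(m)];
          m &= m - 1;
        }
      }
      int K = 0;
      for (uint32_t m = un; m;) {
        K = std::max(K, cnt[__builtin_ctz(m)]);
        m &= m - 1;
      }
      uint32_t keep = 0;
      for (uint32_t m = un; m;) {
        int s = __builtin_ctz(m);
        if (cnt[s] == K) keep |= (1u << s);
        m &= m - 1;
      }
      Su[c] = keep;
      out[c] += (int)ch.size() - K;
    }
  }
  return out;
}

// Canonical topology key of an arbitrary (possibly polytomous) tree.
// [[Rcpp::export]]
std::string cpp_tree_key(IntegerMatrix edge, int ntip) {
  if (ntip > 64) stop("at most 64 tips supported");
  GTree t = gtree_from_edge(edge, ntip);
  int rtip = -1;
  for (int i = 0; i < ntip; ++i)
    if (!t.adj[i].empty()) {
      rtip = i;
      break;
    }
  if (rtip < 0) stop("tree has no tips");
  int root = t.adj[rtip][0];
  std::vector<int> order, parent;
  preorder_g(t, root, rtip, order, parent);
  std::vector<uint64_t> below(t.adj.size(), 0);
  int present = 0;
  for (int i = 0; i < ntip; ++i)
    if (!t.adj[i].empty()) ++present;
  for (size_t oi = order.size(); oi-- > 0;) {
    int u = order[oi];
    if (u < ntip) {
      below[u] = 1ULL << u;
    } else {
      for (int v : t.adj[u])
        if (v != parent[u]) below[u] |= below[v];
    }
  }
  std::vector<uint64_t> key;
  for (int u : order) {
    if (u == root) continue;
    int pc = __builtin_popcountll(below[u]);
    if (pc >= 2 && pc <= present - 2) key.push_back(below[u]);
  }
  std::sort(key.begin(), key.end());
  key.erase(std::unique(key.begin(), key.end()), key.end());
  std::ostringstream os;
  for (uint64_t k : key) os << std::hex << k << ";";
  return os.str();
}

// Root a tree on the edge (u1,v1) by subdividing it with a new root node.
// [[Rcpp::export]]
IntegerMatrix cpp_root_on_edge(IntegerMatrix edge, int ntip, int u1, int v1) {
  GTree t = gtree_from_edge(edge, ntip);
  int nn = (int)t.adj.size();
  t.adj.push_back({});
  int u = u1 - 1, v = v1 - 1;
  t.adj[u].erase(std::find(t.adj[u].begin(), t.adj[u].end(), v));
  t.adj[v].erase(std::find(t.adj[v].begin(), t.adj[v].end(), u));
  t.adj[nn].push_back(u);
  t.adj[nn].push_back(v);
  t.adj[u].push_back(nn);
  t.adj[v].push_back(nn);
  std::vector<int> order, parent;
  preorder_g(t, nn, -1, order, parent);
  int nedge = (int)order.size() - 1;
  IntegerMatrix out(nedge, 2);
  std::vector<int> newid(t.adj.size(), 0);
  int nexti = ntip + 1;
  for (int uu : order) newid[uu] = (uu < ntip) ? (uu + 1) : nexti++;
  int r = 0;
  for (int uu : order) {
    if (uu == nn) continue;
    out(r, 0) = newid[parent[uu]];
    out(r, 1) = newid[uu];
    ++r;
  }
  return out;
}
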