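#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <set>
using namespace Rcpp;

struct EdgeList;
std::vector<uint64_t> split_masks_fwd(const struct EdgeList& E, int nTip);

// ---------------------------------------------------------------------------
// Minimum-change (Fitch/Hartigan) scoring of unordered multistate characters
// on a tree. Leaves carry state-set bitmasks (bit s => state s allowed), so
// polymorphic and missing cells cost nothing at the tip itself. The
// bottom-up max-count rule gives the exact minimum number of changes on
// arbitrary (multifurcating) trees and reduces to the classic Fitch
// intersection/union rule on binary trees.
//
// Edge matrices are treated as UNDIRECTED (the score is root-invariant);
// tips are nodes 1..nTip, matching the mask rows. Internal node ids are
// arbitrary integers above nTip.
// ---------------------------------------------------------------------------

struct EdgeList {
  std::vector<int> u, v;
  int m() const { return (int)u.size(); }
};

static int score_edges(const EdgeList& E, int nTip, const int* masks,
                       int nChar, int nStates, int bound) {
  const int nEdge = E.m();
  int maxNode = nTip;
  for (int e = 0; e < nEdge; ++e) {
    if (E.u[e] > maxNode) maxNode = E.u[e];
    if (E.v[e] > maxNode) maxNode = E.v[e];
  }
  std::vector<int> deg(maxNode + 1, 0);
  for (int e = 0; e < nEdge; ++e) { deg[E.u[e]]++; deg[E.v[e]]++; }
  std::vector<int> adjStart(maxNode + 2, 0);
  for (int w = 1; w <= maxNode; ++w) adjStart[w + 1] = adjStart[w] + deg[w];
  std::vector<int> adjList(2 * nEdge);
  std::vector<int> fill(maxNode + 1, 0);
  for (int e = 0; e < nEdge; ++e) {
    adjList[adjStart[E.u[e]] + fill[E.u[e]]++] = E.v[e];
    adjList[adjStart[E.v[e]] + fill[E.v[e]]++] = E.u[e];
  }
  int root = -1;
  for (int e = 0; e < nEdge && root < 0; ++e) {
    if (E.u[e] > nTip) root = E.u[e];
    else if (E.v[e] > nTip) root = E.v[e];
  }
  if (root < 0) root = E.u[0]; // two-leaf tree
  std::vector<int> par(maxNode + 1, 0), order;
  order.reserve(maxNode);
  std::vector<int> stack;
  stack.push_back(root);
  par[root] = -1;
  while (!stack.empty()) {
    int w = stack.back(); stack.pop_back();
    order.push_back(w);
    for (int k = adjStart[w]; k < adjStart[w + 1]; ++k) {
      int c = adjList[k];
      if (c != par[w]) { par[c] = w; if (c > nTip) stack.push_back(c); }
    }
  }
  std::reverse(order.begin(), order.end());

  std::vector<int> nodeMask(maxNode + 1, 0);
  int tot = 0;
  for (int ch = 0; ch < nChar; ++ch) {
    const int* col = masks + (size_t)ch * nTip;
    for (int t = 1; t <= nTip; ++t) nodeMask[t] = col[t - 1];
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int w = order[oi];
      if (w <= nTip) continue;
      int cnt[10] = {0};
      int nKids = 0;
      for (int k = adjStart[w]; k < adjStart[w + 1]; ++k) {
        int c = adjList[k];
        if (c == par[w]) continue;
        ++nKids;
        int msk = nodeMask[c];
        for (int s = 0; s < nStates; ++s)
          if (msk & (1 << s)) cnt[s]++;
      }
      if (nKids == 0) { nodeMask[w] = (1 << nStates) - 1; continue; }
      int best = 0;
      for (int s = 0; s < nStates; ++s) if (cnt[s] > best) best = cnt[s];
      int msk = 0;
      for (int s = 0; s < nStates; ++s) if (cnt[s] == best) msk |= (1 << s);
      nodeMask[w] = msk;
      tot += nKids - best;
    }
    if (tot > bound) return tot;
  }
  return tot;
}

static EdgeList edgelist_from_matrix(const IntegerMatrix& edge) {
  EdgeList E;
  const int m = edge.nrow();
  E.u.resize(m); E.v.resize(m);
  for (int e = 0; e < m; ++e) { E.u[e] = edge(e, 0); E.v[e] = edge(e, 1); }
  return E;
}

static IntegerMatrix matrix_from_edgelist(const EdgeList& E) {
  IntegerMatrix out(E.m(), 2);
  for (int e = 0; e < E.m(); ++e) { out(e, 0) = E.u[e]; out(e, 1) = E.v[e]; }
  return out;
}

// [[Rcpp::export]]
IntegerVector fitch_counts_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                               int nStates) {
  EdgeList E = edgelist_from_matrix(edge);
  const int nChar = masks.ncol();
  IntegerVector counts(nChar);
  // score one character at a time through the shared kernel
  std::vector<int> col(nTip);
  for (int ch = 0; ch < nChar; ++ch) {
    for (int t = 0; t < nTip; ++t) col[t] = masks(t, ch);
    counts[ch] = score_edges(E, nTip, col.data(), 1, nStates, INT_MAX - 1);
  }
  return counts;
}

// [[Rcpp::export]]
int fitch_total_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                    int nStates, int bound) {
  EdgeList E = edgelist_from_matrix(edge);
  return score_edges(E, nTip, &masks[0], masks.ncol(), nStates, bound);
}

// ---------------------------------------------------------------------------
// Tree-bisection-reconnection enumeration.
// Bisect every edge; suppress the freed endpoint on each fragment (a lone
// leaf fragment stays as is); reconnect every edge (or the lone leaf) of
// one fragment to every edge of the other through the freed node ids.
// Combinations reconstructing the input topology via the same cut are
// skipped.
// ---------------------------------------------------------------------------

struct Fragment {
  bool isLeaf;
  int leafNode;
  EdgeList E;      // after suppression
  int suppressed;  // index of the edge created by suppression (-1 if none)
  int freeNode;    // the suppressed internal node id
};

static void component_of(const EdgeList& E, int cut, int start,
                         std::vector<char>& inComp, int maxNode) {
  std::fill(inComp.begin(), inComp.end(), 0);
  std::vector<int> stack;
  stack.push_back(start);
  inComp[start] = 1;
  while (!stack.empty()) {
    int w = stack.back(); stack.pop_back();
    for (int e = 0; e < E.m(); ++e) {
      if (e == cut) continue;
      int other = -1;
      if (E.u[e] == w) other = E.v[e];
      else if (E.v[e] == w) other = E.u[e];
      if (other >= 0 && !inComp[other]) { inComp[other] = 1; stack.push_back(other); }
    }
  }
}

static Fragment make_fragment(const EdgeList& E, const std::vector<int>& rows,
                              int endNode) {
  Fragment f;
  if (rows.empty()) {
    f.isLeaf = true; f.leafNode = endNode; f.suppressed = -1; f.freeNode = -1;
    return f;
  }
  f.isLeaf = false;
  f.leafNode = -1;
  f.freeNode = endNode;
  int nb1 = -1, nb2 = -1;
  for (size_t k = 0; k < rows.size(); ++k) {
    int e = rows[k];
    int other = -1;
    if (E.u[e] == endNode) other = E.v[e];
    else if (E.v[e] == endNode) other = E.u[e];
    if (other >= 0) { if (nb1 < 0) nb1 = other; else nb2 = other; continue; }
    f.E.u.push_back(E.u[e]);
    f.E.v.push_back(E.v[e]);
  }
  f.E.u.push_back(nb1);
  f.E.v.push_back(nb2);
  f.suppressed = f.E.m() - 1;
  return f;
}

// fn(candidate EdgeList) -> true to stop enumeration
template <typename F>
static bool tbr_enumerate(const EdgeList& E, int nTip, F&& fn) {
  const int m = E.m();
  int maxNode = 0;
  for (int e = 0; e < m; ++e)
    maxNode = std::max(maxNode, std::max(E.u[e], E.v[e]));
  std::vector<char> inComp(maxNode + 1, 0);
  for (int r = 0; r < m; ++r) {
    component_of(E, r, E.u[r], inComp, maxNode);
    std::vector<int> rowsU, rowsV;
    for (int e = 0; e < m; ++e) {
      if (e == r) continue;
      if (inComp[E.u[e]] && inComp[E.v[e]]) rowsU.push_back(e);
      else rowsV.push_back(e);
    }
    Fragment fu = make_fragment(E, rowsU, E.u[r]);
    Fragment fv = make_fragment(E, rowsV, E.v[r]);
    if (fu.isLeaf && fv.isLeaf) continue;
    EdgeList cand;
    if (fu.isLeaf || fv.isLeaf) {
      const Fragment& leaf = fu.isLeaf ? fu : fv;
      const Fragment& tree = fu.isLeaf ? fv : fu;
      for (int ib = 0; ib < tree.E.m(); ++ib) {
        if (ib == tree.suppressed) continue; // reconstructs the input
        cand.u.clear(); cand.v.clear();
        for (int e = 0; e < tree.E.m(); ++e) {
          if (e == ib) continue;
          cand.u.push_back(tree.E.u[e]); cand.v.push_back(tree.E.v[e]);
        }
        cand.u.push_back(tree.E.u[ib]); cand.v.push_back(tree.freeNode);
        cand.u.push_back(tree.E.v[ib]); cand.v.push_back(tree.freeNode);
        cand.u.push_back(tree.freeNode); cand.v.push_back(leaf.leafNode);
        if (fn(cand)) return true;
      }
    } else {
      for (int ia = 0; ia < fu.E.m(); ++ia) {
        for (int ib = 0; ib < fv.E.m(); ++ib) {
          if (ia == fu.suppressed && ib == fv.suppressed) continue; // input
          cand.u.clear(); cand.v.clear();
          for (int e = 0; e < fu.E.m(); ++e) {
            if (e == ia) continue;
            cand.u.push_back(fu.E.u[e]); cand.v.push_back(fu.E.v[e]);
          }
          for (int e = 0; e < fv.E.m(); ++e) {
            if (e == ib) continue;
            cand.u.push_back(fv.E.u[e]); cand.v.push_back(fv.E.v[e]);
          }
          cand.u.push_back(fu.E.u[ia]); cand.v.push_back(fu.freeNode);
          cand.u.push_back(fu.E.v[ia]); cand.v.push_back(fu.freeNode);
          cand.u.push_back(fv.E.u[ib]); cand.v.push_back(fv.freeNode);
          cand.u.push_back(fv.E.v[ib]); cand.v.push_back(fv.freeNode);
          cand.u.push_back(fu.freeNode); cand.v.push_back(fv.freeNode);
          if (fn(cand)) return true;
        }
      }
    }
  }
  return false;
}

// One TBR improvement pass. Returns list(edge=..., length=, tried=) where
// edge has 0 rows if no neighbor is shorter. steepest=TRUE scans the whole
// neighborhood; otherwise the first shorter neighbor is returned.
// [[Rcpp::export]]
List tbr_improve_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                     int nStates, int curLen, bool steepest) {
  EdgeList E = edgelist_from_matrix(edge);
  const int nChar = masks.ncol();
  int tried = 0;
  int bestLen = curLen;
  EdgeList best;
  bool found = false;
  tbr_enumerate(E, nTip, [&](const EdgeList& cand) {
    ++tried;
    int len = score_edges(cand, nTip, &masks[0], nChar, nStates, bestLen - 1);
    if (len < bestLen) {
      bestLen = len;
      best = cand;
      found = true;
      if (!steepest) return true;
    }
    return false;
  });
  return List::create(
    _["edge"] = found ? matrix_from_edgelist(best) : IntegerMatrix(0, 2),
    _["length"] = bestLen, _["tried"] = tried);
}

// All neighbors with length <= cap, plus the strictly-better one if found
// (search restarts from it). Duplicate topologies are not filtered here.
// [[Rcpp::export]]
List tbr_within_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                    int nStates, int cap, int maxCollect) {
  EdgeList E = edgelist_from_matrix(edge);
  const int nChar = masks.ncol();
  std::vector<IntegerMatrix> equal;
  std::vector<int> lens;
  bool capped = false;
  tbr_enumerate(E, nTip, [&](const EdgeList& cand) {
    int len = score_edges(cand, nTip, &masks[0], nChar, nStates, cap);
    if (len <= cap) {
      equal.push_back(matrix_from_edgelist(cand));
      lens.push_back(len);
      if ((int)equal.size() >= maxCollect) { capped = true; return true; }
    }
    return false;
  });
  List out(equal.size());
  for (size_t i = 0; i < equal.size(); ++i) out[i] = equal[i];
  return List::create(_["edges"] = out, _["lengths"] = wrap(lens),
                      _["capped"] = capped);
}

// All distinct TBR neighbor topologies (signatures differing from input).
// [[Rcpp::export]]
List tbr_neighbors_cpp(IntegerMatrix edge, int nTip) {
  if (nTip > 62) stop("TBR neighbor enumeration supports up to 62 tips");
  EdgeList E = edgelist_from_matrix(edge);
  std::set<std::vector<uint64_t> > seen;
  std::vector<IntegerMatrix> out;
  std::vector<uint64_t> selfSig = split_masks_fwd(E, nTip);
  tbr_enumerate(E, nTip, [&](const EdgeList& cand) {
    std::vector<uint64_t> sig = split_masks_fwd(cand, nTip);
    if (sig != selfSig && seen.insert(sig).second)
      out.push_back(matrix_from_edgelist(cand));
    return false;
  });
  List res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i];
  return res;
}

// ---------------------------------------------------------------------------
// Canonical unrooted split signatures (<= 62 tips, 64-bit masks). A split
// is represented by the tip set on the side NOT containing tip 1; trivial
// splits are dropped; the signature is the sorted mask vector.
// ---------------------------------------------------------------------------

static std::vector<uint64_t> split_masks(const EdgeList& E, int nTip) {
  const int m = E.m();
  int maxNode = nTip;
  for (int e = 0; e < m; ++e)
    maxNode = std::max(maxNode, std::max(E.u[e], E.v[e]));
  // orient from an internal root, collect subtree tip masks bottom-up
  std::vector<std::vector<int> > adj(maxNode + 1);
  for (int e = 0; e < m; ++e) {
    adj[E.u[e]].push_back(E.v[e]);
    adj[E.v[e]].push_back(E.u[e]);
  }
  int root = -1;
  for (int e = 0; e < m && root < 0; ++e) {
    if (E.u[e] > nTip) root = E.u[e];
    else if (E.v[e] > nTip) root = E.v[e];
  }
  if (root < 0) return std::vector<uint64_t>();
  std::vector<int> par(maxNode + 1, 0), order;
  std::vector<int> stack;
  stack.push_back(root);
  par[root] = -1;
  while (!stack.empty()) {
    int w = stack.back(); stack.pop_back();
    order.push_back(w);
    for (size_t k = 0; k < adj[w].size(); ++k) {
      int c = adj[w][k];
      if (c != par[w]) { par[c] = w; if (c > nTip) stack.push_back(c); }
    }
  }
  std::vector<uint64_t> below(maxNode + 1, 0);
  for (int t = 1; t <= nTip; ++t) below[t] = (uint64_t)1 << (t - 1);
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int w = order[i];
    if (w <= nTip) continue;
    for (size_t k = 0; k < adj[w].size(); ++k) {
      int c = adj[w][k];
      if (c != par[w]) below[w] |= below[c];
    }
  }
  const uint64_t full = (nTip == 64) ? ~(uint64_t)0
                                     : (((uint64_t)1 << nTip) - 1);
  std::vector<uint64_t> sigs;
  for (int w = 1; w <= maxNode; ++w) {
    if (w == root || par[w] <= 0) continue;
    uint64_t msk = below[w];
    if (msk & 1) msk = full & ~msk;
    int pc = __builtin_popcountll(msk);
    if (pc < 2 || pc > nTip - 2) continue;
    sigs.push_back(msk);
  }
  std::sort(sigs.begin(), sigs.end());
  sigs.erase(std::unique(sigs.begin(), sigs.end()), sigs.end());
  return sigs;
}

std::vector<uint64_t> split_masks_fwd(const EdgeList& E, int nTip) {
  return split_masks(E, nTip);
}

// [[Rcpp::export]]
String edge_signature_cpp(IntegerMatrix edge, int nTip) {
  if (nTip > 62) stop("signatures support up to 62 tips");
  EdgeList E = edgelist_from_matrix(edge);
  std::vector<uint64_t> sigs = split_masks(E, nTip);
  std::string s;
  char buf[20];
  for (size_t i = 0; i < sigs.size(); ++i) {
    snprintf(buf, sizeof(buf), "%llx|", (unsigned long long)sigs[i]);
    s += buf;
  }
  return String(s);
}

// Nontrivial splits as tip-index vectors (canonical side excluding tip 1).
// [[Rcpp::export]]
List edge_splits_cpp(IntegerMatrix edge, int nTip) {
  if (nTip > 62) stop("splits support up to 62 tips");
  EdgeList E = edgelist_from_matrix(edge);
  std::vector<uint64_t> sigs = split_masks(E, nTip);
  List out(sigs.size());
  for (size_t i = 0; i < sigs.size(); ++i) {
    std::vector<int> tips;
    for (int t = 0; t < nTip; ++t)
      if (sigs[i] & ((uint64_t)1 << t)) tips.push_back(t + 1);
    out[i] = wrap(tips);
  }
  return out;
}
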