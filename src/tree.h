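#ifndef MORPHOBENCH_TREE_H
#define MORPHOBENCH_TREE_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>

// Unrooted binary trees are held rooted at a trifurcating node (the ape
// convention for unrooted phylo objects); rooted generating trees keep a
// bifurcating root.  Node indices are 0-based: tips 0..ntip-1, internals
// ntip..nnode-1.  blen[v] is the length of the edge above v.
struct Tree {
  int ntip = 0;
  int nnode = 0;
  int root = -1;
  std::vector<int> parent;                 // -1 at root
  std::vector<std::array<int, 3>> child;   // -1 when unused
  std::vector<int> nchild;
  std::vector<double> blen;
  std::vector<int> post;                   // postorder, root last

  void alloc(int n_nodes) {
    nnode = n_nodes;
    parent.assign(nnode, -1);
    child.assign(nnode, {-1, -1, -1});
    nchild.assign(nnode, 0);
    blen.assign(nnode, 0.0);
    post.clear();
  }

  void add_child(int p, int c) {
    if (nchild[p] >= 3)
      Rcpp::stop("tree has a node of degree > 3; a binary tree is required");
    child[p][nchild[p]++] = c;
    parent[c] = p;
  }

  // replace child `oldc` of `p` with `newc` (parent pointer of newc updated;
  // oldc's parent pointer is left to the caller)
  void swap_child(int p, int oldc, int newc) {
    for (int i = 0; i < nchild[p]; ++i)
      if (child[p][i] == oldc) { child[p][i] = newc; break; }
    parent[newc] = p;
  }

  void remove_child(int p, int c) {
    int j = 0;
    for (int i = 0; i < nchild[p]; ++i)
      if (child[p][i] != c) child[p][j++] = child[p][i];
    for (int i = j; i < 3; ++i) child[p][i] = -1;
    nchild[p] = j;
  }

  void compute_postorder() {
    post.clear();
    post.reserve(nnode);
    // iterative DFS
    std::vector<int> stack;
    std::vector<int> state(nnode, 0);
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back();
      if (state[v] < nchild[v]) {
        stack.push_back(child[v][state[v]++]);
      } else {
        post.push_back(v);
        stack.pop_back();
      }
    }
  }
};

// Build a Tree from an ape edge matrix (1-based node numbers, tips 1..ntip).
inline Tree tree_from_edge(const Rcpp::IntegerMatrix& edge,
                           const Rcpp::NumericVector& edge_len,
                           int ntip) {
  int nnode = ntip;
  for (int i = 0; i < edge.nrow(); ++i) {
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  }
  Tree tr;
  tr.ntip = ntip;
  tr.alloc(nnode);
  std::vector<bool> is_child(nnode, false);
  for (int i = 0; i < edge.nrow(); ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    tr.add_child(p, c);
    is_child[c] = true;
    if (edge_len.size() == edge.nrow()) tr.blen[c] = edge_len[i];
  }
  for (int v = ntip; v < nnode; ++v)
    if (!is_child[v]) { tr.root = v; break; }
  tr.compute_postorder();
  return tr;
}

// Export back to an ape-style edge matrix with internals renumbered in
// preorder so that the root is ntip+1 (cladewise order).
inline void tree_to_edge(const Tree& tr, Rcpp::IntegerMatrix& edge,
                         Rcpp::NumericVector& edge_len) {
  std::vector<int> newid(tr.nnode, 0);
  for (int v = 0; v < tr.ntip; ++v) newid[v] = v + 1;
  int next = tr.ntip + 1;
  std::vector<int> stack{tr.root};
  std::vector<std::pair<int, int>> rows;  // (old parent, old child) preorder
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v >= tr.ntip) newid[v] = next++;
    for (int i = tr.nchild[v] - 1; i >= 0; --i) stack.push_back(tr.child[v][i]);
    if (v != tr.root) rows.emplace_back(tr.parent[v], v);
  }
  // rows currently in discovery order of the child: that is preorder
  for (size_t i = 0; i < rows.size(); ++i) {
    edge(i, 0) = newid[rows[i].first];
    edge(i, 1) = newid[rows[i].second];
    edge_len[i] = tr.blen[rows[i].second];
  }
}

// splitmix64: small, fast, deterministic across platforms.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

// Per-character Fitch step counts on a (possibly trifurcating-rooted) tree.
// states: ntip x nchar, values 0..7.  Multifurcations are combined
// sequentially, which is exact for a trifurcating root (it equals rooting
// the unrooted tree along one of the root edges).
inline void fitch_counts(const Tree& tr, const Rcpp::IntegerMatrix& states,
                         std::vector<int>& steps) {
  const int nchar = states.ncol();
  steps.assign(nchar, 0);
  std::vector<uint8_t> mask(tr.nnode);
  for (int ch = 0; ch < nchar; ++ch) {
    int st = 0;
    for (int idx : tr.post) {
      if (idx < tr.ntip) {
        mask[idx] = (uint8_t)(1u << states(idx, ch));
      } else {
        uint8_t m = mask[tr.child[idx][0]];
        for (int i = 1; i < tr.nchild[idx]; ++i) {
          uint8_t c = mask[tr.child[idx][i]];
          uint8_t inter = m & c;
          if (inter) m = inter; else { m |= c; ++st; }
        }
        mask[idx] = m;
      }
    }
    steps[ch] = st;
  }
}

#endif
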