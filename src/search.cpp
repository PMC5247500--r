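#include "tree.h"
#include <map>
#include <array>
using namespace Rcpp;

namespace {

struct Scorer {
  // Parsimony-uninformative characters have the same length on every
  // topology; they are scored once into `base` and removed, and duplicate
  // informative columns are collapsed into weighted patterns.
  IntegerMatrix states;        // informative patterns only
  std::vector<int> minsteps;   // per pattern
  std::vector<double> weights; // duplicate-column multiplicities
  double base = 0.0;           // constant EW steps of uninformative columns
  double k_iw;                 // <= 0 means equal weights
  std::vector<int> steps;
  long n_eval = 0;

  Scorer(const IntegerMatrix& st, const std::vector<int>& ms, double k)
    : k_iw(k) {
    const int ntip = st.nrow();
    std::map<std::vector<int>, double> pat;
    for (int ch = 0; ch < st.ncol(); ++ch) {
      std::array<int, 8> count{};
      for (int i = 0; i < ntip; ++i) count[st(i, ch)]++;
      int present = 0, multi = 0;
      for (int c : count) {
        present += c > 0;
        multi += c >= 2;
      }
      if (multi < 2) {           // uninformative: length = states - 1 always
        base += present - 1;
        continue;
      }
      std::vector<int> col(ntip + 1);
      for (int i = 0; i < ntip; ++i) col[i] = st(i, ch);
      col[ntip] = ms[ch];
      pat[col] += 1.0;
    }
    states = IntegerMatrix(ntip, (int)pat.size());
    int j = 0;
    for (auto& kv : pat) {
      for (int i = 0; i < ntip; ++i) states(i, j) = kv.first[i];
      minsteps.push_back(kv.first[ntip]);
      weights.push_back(kv.second);
      ++j;
    }
  }

  // cost to MINIMIZE: total steps (EW) or sum e/(e+k) (IW); uninformative
  // characters contribute `base` (EW) or nothing (IW, e = 0)
  double operator()(Tree& tr) {
    tr.compute_postorder();
    fitch_counts(tr, states, steps);
    ++n_eval;
    if (k_iw <= 0) {
      double s = base;
      for (size_t i = 0; i < steps.size(); ++i) s += weights[i] * steps[i];
      return s;
    }
    double c = 0.0;
    for (size_t i = 0; i < steps.size(); ++i) {
      // on partial trees (stepwise addition) steps can fall below the
      // global minimum; clamp so the fit stays finite (full trees always
      // have e >= 0)
      double e = std::max(0, steps[i] - minsteps[i]);
      c += weights[i] * e / (e + k_iw);
    }
    return c;
  }
};

typedef std::vector<uint64_t> Signature;

Signature tree_signature(Tree& tr) {
  tr.compute_postorder();
  std::vector<uint64_t> mask(tr.nnode, 0);
  Signature sig;
  uint64_t full = (tr.ntip == 64) ? ~0ULL : ((1ULL << tr.ntip) - 1);
  for (int v : tr.post) {
    if (v < tr.ntip) mask[v] = 1ULL << v;
    else
      for (int i = 0; i < tr.nchild[v]; ++i) mask[v] |= mask[tr.child[v][i]];
    if (v >= tr.ntip && v != tr.root) {
      uint64_t m = mask[v];
      int pc = __builtin_popcountll(m);
      if (pc < 2 || pc > tr.ntip - 2) continue;
      sig.push_back((m & 1ULL) ? (full & ~m) : m);
    }
  }
  std::sort(sig.begin(), sig.end());
  return sig;
}

struct Backup {
  std::vector<int> parent, nchild;
  std::vector<std::array<int, 3>> child;
  void save(const Tree& tr) {
    parent = tr.parent; nchild = tr.nchild; child = tr.child;
  }
  void restore(Tree& tr) const {
    tr.parent = parent; tr.nchild = nchild; tr.child = child;
  }
};

struct NNIMove { int u, v, b, c; };

void enumerate_nni(const Tree& tr, std::vector<NNIMove>& out) {
  out.clear();
  for (int v = tr.ntip; v < tr.nnode; ++v) {
    if (v == tr.root || tr.nchild[v] == 0) continue;
    int u = tr.parent[v];
    if (u == tr.root) {
      int b = tr.child[v][0];
      for (int i = 0; i < tr.nchild[u]; ++i) {
        int c = tr.child[u][i];
        if (c != v) out.push_back({u, v, b, c});
      }
    } else {
      int c = (tr.child[u][0] == v) ? tr.child[u][1] : tr.child[u][0];
      out.push_back({u, v, tr.child[v][0], c});
      out.push_back({u, v, tr.child[v][1], c});
    }
  }
}

void apply_nni(Tree& tr, const NNIMove& m) {
  tr.swap_child(m.v, m.b, m.c);
  tr.swap_child(m.u, m.c, m.b);
}

// random stepwise-addition starting tree
void random_addition(Tree& tr, Scorer& score, RNG& rng) {
  int ntip = tr.ntip;
  tr.alloc(2 * ntip - 2);
  tr.ntip = ntip;
  std::vector<int> ord(ntip);
  for (int i = 0; i < ntip; ++i) ord[i] = i;
  for (int i = ntip - 1; i > 0; --i)
    std::swap(ord[i], ord[rng.unif_int(i + 1)]);
  tr.root = ntip;
  tr.add_child(ntip, ord[0]);
  tr.add_child(ntip, ord[1]);
  tr.add_child(ntip, ord[2]);
  std::vector<int> active{ord[0], ord[1], ord[2]};
  int next_internal = ntip + 1;
  for (int i = 3; i < ntip; ++i) {
    int x = ord[i], m = next_internal++;
    double best = HUGE_VAL;
    std::vector<int> ties;
    for (int w : active) {
      int p = tr.parent[w];
      tr.swap_child(p, w, m);
      tr.nchild[m] = 0;
      tr.child[m] = {-1, -1, -1};
      tr.add_child(m, w);
      tr.add_child(m, x);
      double c = score(tr);
      if (c < best - 1e-9) {
        best = c;
        ties.clear();
        ties.push_back(w);
      } else if (c < best + 1e-9) {
        ties.push_back(w);
      }
      tr.swap_child(p, m, w);  // undo
    }
    int w = ties[rng.unif_int((int)ties.size())];
    int p = tr.parent[w];
    tr.swap_child(p, w, m);
    tr.nchild[m] = 0;
    tr.child[m] = {-1, -1, -1};
    tr.add_child(m, w);
    tr.add_child(m, x);
    active.push_back(x);
    active.push_back(m);
  }
  tr.compute_postorder();
}

// prune node i (whose parent is not the root) and regraft above j;
// returns false if the (i, j) pair is invalid
bool apply_spr(Tree& tr, int i, int j) {
  if (i == tr.root || i < 0) return false;
  int p = tr.parent[i];
  if (p == tr.root || p < 0) return false;
  if (j == tr.root || j == p || j == i) return false;
  // j must not be inside the pruned subtree
  for (int a = j; a != -1; a = tr.parent[a])
    if (a == i || a == p) return false;
  int g = tr.parent[p];
  int c = (tr.child[p][0] == i) ? tr.child[p][1] : tr.child[p][0];
  if (j == c) return false;  // regraft in place: identity
  tr.swap_child(g, p, c);
  int q = tr.parent[j];
  tr.swap_child(q, j, p);
  tr.swap_child(p, c, j);
  return true;
}

}  // namespace

// [[Rcpp::export]]
List parsimony_search_cpp(IntegerMatrix states, IntegerVector minsteps,
                          double k_iw, int n_starts, int max_rounds,
                          bool use_spr, int spr_per_round, int max_trees,
                          int plateau_steps, double seed) {
  const int ntip = states.nrow();
  Scorer score(states, as<std::vector<int>>(minsteps), k_iw);
  RNG rng((uint64_t)seed);

  double best_cost = HUGE_VAL;
  std::map<Signature, Backup> best_pool;
  std::vector<NNIMove> moves;

  auto consider = [&](Tree& tr, double cost) {
    if (cost < best_cost - 1e-9) {
      best_cost = cost;
      best_pool.clear();
    }
    if (cost < best_cost + 1e-9 && (int)best_pool.size() < max_trees) {
      Backup b;
      b.save(tr);
      best_pool.emplace(tree_signature(tr), b);
    }
  };

  for (int s = 0; s < n_starts; ++s) {
    Tree tr;
    tr.ntip = ntip;
    random_addition(tr, score, rng);
    double cur = score(tr);
    for (int round = 0; round < max_rounds; ++round) {
      bool improved = false;
      // steepest-ascent NNI sweep
      enumerate_nni(tr, moves);
      double bestn = cur;
      int besti = -1;
      for (size_t k = 0; k < moves.size(); ++k) {
        apply_nni(tr, moves[k]);
        double c = score(tr);
        apply_nni(tr, {moves[k].u, moves[k].v, moves[k].c, moves[k].b});
        if (c < bestn - 1e-9) { bestn = c; besti = (int)k; }
      }
      if (besti >= 0) {
        apply_nni(tr, moves[besti]);
        cur = bestn;
        improved = true;
      }
      if (use_spr) {
        Backup bk;
        for (int a = 0; a < spr_per_round; ++a) {
          int i = rng.unif_int(tr.nnode), j = rng.unif_int(tr.nnode);
          bk.save(tr);
          if (!apply_spr(tr, i, j)) continue;
          double c = score(tr);
          if (c < cur - 1e-9) { cur = c; improved = true; }
          else bk.restore(tr);
        }
      }
      if (!improved) break;
    }
    tr.compute_postorder();
    consider(tr, cur);
    // equally good NNI neighbours of a tied local optimum join the pool
    if (cur < best_cost + 1e-9) {
      enumerate_nni(tr, moves);
      for (const NNIMove& m : moves) {
        apply_nni(tr, m);
        double c = score(tr);
        if (c < best_cost + 1e-9) consider(tr, c);
        apply_nni(tr, {m.u, m.v, m.c, m.b});
      }
    }
  }

  // Random equal-score NNI walks over the optimal plateau: hill climbing
  // alone finds few of the many tied optimal topologies, and the
  // majority-rule consensus of the optimal set is only meaningful if the
  // tied set is sampled broadly.
  if (plateau_steps > 0 && !best_pool.empty()) {
    std::vector<Backup> seeds_bk;
    for (auto& kv : best_pool) {
      seeds_bk.push_back(kv.second);
      if ((int)seeds_bk.size() >= 5) break;
    }
    for (const Backup& b : seeds_bk) {
      Tree tr;
      tr.ntip = ntip;
      tr.alloc(2 * ntip - 2);
      b.restore(tr);
      tr.nnode = (int)tr.parent.size();
      tr.root = ntip;
      for (int v = ntip; v < tr.nnode; ++v)
        if (tr.parent[v] == -1 && tr.nchild[v] > 0) tr.root = v;
      for (int step = 0; step < plateau_steps; ++step) {
        enumerate_nni(tr, moves);
        const NNIMove& m = moves[rng.unif_int((int)moves.size())];
        apply_nni(tr, m);
        double c = score(tr);
        if (c < best_cost + 1e-9) {
          consider(tr, c);          // stay on (or below) the plateau
        } else {
          apply_nni(tr, {m.u, m.v, m.c, m.b});
        }
      }
    }
  }

  List trees((int)best_pool.size());
  int idx = 0;
  for (auto& kv : best_pool) {
    Tree tr;
    tr.ntip = ntip;
    tr.alloc(2 * ntip - 2);
    kv.second.restore(tr);
    tr.root = ntip;
    // restore() overwrote alloc's sizing with the saved arrays
    tr.nnode = (int)tr.parent.size();
    for (int v = ntip; v < tr.nnode; ++v)
      if (tr.parent[v] == -1 && tr.nchild[v] > 0) tr.root = v;
    tr.compute_postorder();
    IntegerMatrix em(tr.nnode - 1, 2);
    NumericVector el(tr.nnode - 1);
    tree_to_edge(tr, em, el);
    trees[idx++] = em;
  }
  return List::create(_["cost"] = best_cost, _["trees"] = trees,
                      _["n_evaluated"] = (double)score.n_eval);
}
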