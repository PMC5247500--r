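#ifndef MORPHOBENCH_MK_H
#define MORPHOBENCH_MK_H

#include "tree.h"
#include <cmath>
#include <map>

// Yang-style equal-probability discretized gamma (shape = rate = alpha so the
// mean is 1); category rates are the conditional means of the quantile slices,
// renormalized to mean exactly 1.
inline std::vector<double> discrete_gamma(double alpha, int ncat) {
  std::vector<double> r(ncat, 1.0);
  if (ncat == 1) return r;
  double scale = 1.0 / alpha;
  std::vector<double> q(ncat + 1);
  q[0] = 0.0;
  for (int i = 1; i < ncat; ++i)
    q[i] = R::qgamma((double)i / ncat, alpha, scale, 1, 0);
  double prev = 0.0, sum = 0.0;
  for (int i = 0; i < ncat; ++i) {
    double hi = (i == ncat - 1)
      ? 1.0 : R::pgamma(q[i + 1], alpha + 1.0, scale, 1, 0);
    r[i] = ncat * (hi - prev);
    prev = hi;
    sum += r[i];
  }
  for (int i = 0; i < ncat; ++i) r[i] *= ncat / sum;
  return r;
}

// Pruning engine for the Mk model with discretized gamma rates.  Transition
// probabilities use the k-state symmetric closed form normalized to one
// expected change per unit branch length:
//   P_same(t) = 1/k + (k-1)/k * exp(-k t / (k-1))
//   P_diff(t) = 1/k - 1/k   * exp(-k t / (k-1))
struct MkEngine {
  int ntip = 0, nchar = 0, ncat = 4, nnode = 0;
  std::vector<int> states;   // ntip * nchar, column-major, unique patterns
  std::vector<int> kchar;    // observed-state count per pattern (>= 2)
  std::vector<double> wchar; // pattern weight (duplicate-column count)
  std::vector<int> kset;     // distinct values in kchar
  bool ascertain = false;    // Mkv conditioning on variable characters
  std::vector<double> rates; // gamma category rates, mean 1
  // P cache entries indexed [node * ncat * 3 + cat * 3 + (k - 2)]
  std::vector<double> psame, pdiff;
  std::vector<double> work;  // partials, nnode * 4
  std::vector<double> catll; // per-category site log-likelihood buffer

  void init(const Rcpp::IntegerMatrix& st, const std::vector<int>& kc,
            int n_cat, bool asc) {
    ntip = st.nrow();
    ncat = n_cat;
    ascertain = asc;
    catll.assign(ncat, 0.0);
    // compress duplicate (pattern, state count) columns into weighted
    // site patterns
    std::map<std::vector<int>, double> pat;
    std::vector<int> col(ntip + 1);
    for (int ch = 0; ch < st.ncol(); ++ch) {
      for (int i = 0; i < ntip; ++i) col[i] = st(i, ch);
      col[ntip] = kc[ch];
      pat[col] += 1.0;
    }
    nchar = (int)pat.size();
    states.resize((size_t)ntip * nchar);
    kchar.resize(nchar);
    wchar.resize(nchar);
    int j = 0;
    for (auto& kv : pat) {
      for (int i = 0; i < ntip; ++i)
        states[(size_t)j * ntip + i] = kv.first[i];
      kchar[j] = kv.first[ntip];
      wchar[j] = kv.second;
      ++j;
    }
    kset = kchar;
    std::sort(kset.begin(), kset.end());
    kset.erase(std::unique(kset.begin(), kset.end()), kset.end());
  }

  void set_alpha(double alpha) { rates = discrete_gamma(alpha, ncat); }

  void alloc_cache(int n_nodes) {
    nnode = n_nodes;
    psame.assign((size_t)nnode * ncat * 3, 0.0);
    pdiff.assign((size_t)nnode * ncat * 3, 0.0);
    work.assign((size_t)nnode * 4, 0.0);
  }

  void update_node(const Tree& tr, int v) {
    for (int c = 0; c < ncat; ++c) {
      double t = tr.blen[v] * rates[c];
      for (int k : kset) {
        double e = std::exp(-k * t / (k - 1.0));
        size_t idx = ((size_t)v * ncat + c) * 3 + (k - 2);
        psame[idx] = 1.0 / k + (k - 1.0) / k * e;
        pdiff[idx] = 1.0 / k * (1.0 - e);
      }
    }
  }

  void update_all(const Tree& tr) {
    if (nnode != tr.nnode) alloc_cache(tr.nnode);
    for (int v = 0; v < tr.nnode; ++v)
      if (v != tr.root) update_node(tr, v);
  }

  // log-likelihood of one character (column `ch` of `states`), or of the
  // constant all-zero pattern when ch < 0 (then with k = kc).
  double char_loglik(const Tree& tr, int ch, int kc) {
    const int k = (ch >= 0) ? kchar[ch] : kc;
    const int* col = (ch >= 0) ? &states[(size_t)ch * ntip] : nullptr;
    double maxcat = -HUGE_VAL;
    for (int c = 0; c < ncat; ++c) {
      double logscale = 0.0;
      for (int vi : tr.post) {
        double* L = &work[(size_t)vi * 4];
        if (vi < tr.ntip) {
          int s = (ch >= 0) ? col[vi] : 0;
          for (int a = 0; a < k; ++a) L[a] = 0.0;
          L[s] = 1.0;
        } else if (k == 2) {
          double L0 = 1.0, L1 = 1.0;
          for (int ci = 0; ci < tr.nchild[vi]; ++ci) {
            int w = tr.child[vi][ci];
            size_t idx = ((size_t)w * ncat + c) * 3;
            const double ps = psame[idx], pd = pdiff[idx];
            const double* Lw = &work[(size_t)w * 4];
            L0 *= ps * Lw[0] + pd * Lw[1];
            L1 *= pd * Lw[0] + ps * Lw[1];
          }
          double m = std::max(L0, L1);
          if (m > 0 && m < 1e-120) {
            L0 /= m; L1 /= m;
            logscale += std::log(m);
          }
          L[0] = L0; L[1] = L1;
        } else {
          for (int a = 0; a < k; ++a) L[a] = 1.0;
          for (int ci = 0; ci < tr.nchild[vi]; ++ci) {
            int w = tr.child[vi][ci];
            size_t idx = ((size_t)w * ncat + c) * 3 + (k - 2);
            const double ps = psame[idx], pd = pdiff[idx];
            const double* Lw = &work[(size_t)w * 4];
            double S = 0.0;
            for (int a = 0; a < k; ++a) S += Lw[a];
            for (int a = 0; a < k; ++a)
              L[a] *= pd * S + (ps - pd) * Lw[a];
          }
          double m = L[0];
          for (int a = 1; a < k; ++a) m = std::max(m, L[a]);
          if (m > 0 && m < 1e-120) {
            for (int a = 0; a < k; ++a) L[a] /= m;
            logscale += std::log(m);
          }
        }
      }
      const double* Lr = &work[(size_t)tr.root * 4];
      double s = 0.0;
      for (int a = 0; a < k; ++a) s += Lr[a];
      catll[c] = std::log(s / k) + logscale;
      maxcat = std::max(maxcat, catll[c]);
    }
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(catll[c] - maxcat);
    return maxcat + std::log(acc / ncat);
  }

  double loglik(const Tree& tr) {
    double total = 0.0;
    // Mkv correction: under the symmetric Mk model all k constant patterns
    // have equal likelihood, so P(constant) = k * L(all zeros).
    double log1m_pconst[5] = {0, 0, 0, 0, 0};
    if (ascertain) {
      for (int k : kset) {
        double pc = k * std::exp(char_loglik(tr, -1, k));
        log1m_pconst[k] = std::log1p(-pc);
      }
    }
    for (int ch = 0; ch < nchar; ++ch) {
      double ll = char_loglik(tr, ch, 0);
      if (ascertain) ll -= log1m_pconst[kchar[ch]];
      total += wchar[ch] * ll;
    }
    return total;
  }

  // ---- cached-partials evaluation for MCMC ----
  // Per-node conditional likelihoods are cached across generations; a move
  // marks the path from its perturbed nodes to the root dirty and only those
  // nodes are recomputed.  A rejected move re-marks the same nodes so the
  // next evaluation restores them from the reverted tree.  No per-node
  // rescaling is applied: at the tree sizes the engine targets (tens of
  // taxa) double precision cannot underflow.
  std::vector<double> part;    // [((v * nchar) + ch) * ncat + c] * 4
  std::vector<uint8_t> dirty;

  void cache_init(const Tree& tr) {
    part.assign((size_t)tr.nnode * nchar * ncat * 4, 0.0);
    dirty.assign(tr.nnode, 1);
    for (int v = 0; v < tr.ntip; ++v) {
      for (int ch = 0; ch < nchar; ++ch) {
        int s = states[(size_t)ch * ntip + v];
        for (int c = 0; c < ncat; ++c)
          part[(((size_t)v * nchar + ch) * ncat + c) * 4 + s] = 1.0;
      }
      dirty[v] = 0;
    }
  }

  void mark_path(const Tree& tr, int v) {
    for (; v != -1; v = tr.parent[v])
      if (v >= tr.ntip) dirty[v] = 1;
  }

  void mark_all(const Tree& tr) {
    for (int v = tr.ntip; v < tr.nnode; ++v) dirty[v] = 1;
  }

  double loglik_cached(const Tree& tr) {
    for (int vi : tr.post) {
      if (vi < tr.ntip || !dirty[vi]) continue;
      for (int ch = 0; ch < nchar; ++ch) {
        const int k = kchar[ch];
        for (int c = 0; c < ncat; ++c) {
          double* L = &part[(((size_t)vi * nchar + ch) * ncat + c) * 4];
          if (k == 2) {
            double L0 = 1.0, L1 = 1.0;
            for (int ci = 0; ci < tr.nchild[vi]; ++ci) {
              int w = tr.child[vi][ci];
              size_t idx = ((size_t)w * ncat + c) * 3;
              const double ps = psame[idx], pd = pdiff[idx];
              const double* Lw =
                &part[(((size_t)w * nchar + ch) * ncat + c) * 4];
              L0 *= ps * Lw[0] + pd * Lw[1];
              L1 *= pd * Lw[0] + ps * Lw[1];
            }
            L[0] = L0; L[1] = L1;
          } else {
            for (int a = 0; a < k; ++a) L[a] = 1.0;
            for (int ci = 0; ci < tr.nchild[vi]; ++ci) {
              int w = tr.child[vi][ci];
              size_t idx = ((size_t)w * ncat + c) * 3 + (k - 2);
              const double ps = psame[idx], pd = pdiff[idx];
              const double* Lw =
                &part[(((size_t)w * nchar + ch) * ncat + c) * 4];
              double S = 0.0;
              for (int a = 0; a < k; ++a) S += Lw[a];
              for (int a = 0; a < k; ++a)
                L[a] *= pd * S + (ps - pd) * Lw[a];
            }
          }
        }
      }
      dirty[vi] = 0;
    }
    double log1m_pconst[5] = {0, 0, 0, 0, 0};
    if (ascertain) {
      for (int k : kset) {
        double pc = k * std::exp(char_loglik(tr, -1, k));
        log1m_pconst[k] = std::log1p(-pc);
      }
    }
    double total = 0.0;
    const int r = tr.root;
    for (int ch = 0; ch < nchar; ++ch) {
      const int k = kchar[ch];
      double site = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double* Lr = &part[(((size_t)r * nchar + ch) * ncat + c) * 4];
        double s = 0.0;
        for (int a = 0; a < k; ++a) s += Lr[a];
        site += s / k;
      }
      double ll = std::log(site / ncat);
      if (ascertain) ll -= log1m_pconst[k];
      total += wchar[ch] * ll;
    }
    return total;
  }
};

#endif
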