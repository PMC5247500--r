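#include "tree.h"
#include "mk.h"
using namespace Rcpp;

namespace {

struct Chain {
  Tree tr;
  MkEngine eng;
  double alpha = 1.0;
  double ll = 0.0, lp = 0.0;
  double beta = 1.0;
};

double log_prior(const Tree& tr, double alpha, double bl_rate,
                 double alpha_rate) {
  double lp = R::dexp(alpha, 1.0 / alpha_rate, 1);
  for (int v = 0; v < tr.nnode; ++v)
    if (v != tr.root) lp += R::dexp(tr.blen[v], 1.0 / bl_rate, 1);
  return lp;
}

struct TreeBackup {
  std::vector<int> parent, nchild;
  std::vector<std::array<int, 3>> child;
  std::vector<double> blen;
  void save(const Tree& tr) {
    parent = tr.parent; nchild = tr.nchild; child = tr.child; blen = tr.blen;
  }
  void restore(Tree& tr) const {
    tr.parent = parent; tr.nchild = nchild; tr.child = child; tr.blen = blen;
    tr.compute_postorder();
  }
};

}  // namespace

// Metropolis(-coupled) MCMC over unrooted topologies, branch lengths and the
// gamma shape under Mk+Gamma.  Priors: iid Exponential(bl_rate) branch
// lengths, Exponential(alpha_rate) shape, uniform topology.
// move_weights: (NNI, SPR, branch multiplier, alpha multiplier).
// [[Rcpp::export]]
List mcmc_cpp(IntegerMatrix edge, NumericVector edge_len, int ntip,
              IntegerMatrix states, IntegerVector kchar,
              int ncat, int n_gen, int sample_interval,
              double alpha0, double bl_rate, double alpha_rate,
              NumericVector move_weights, double bl_lambda,
              double alpha_lambda, bool prior_only, bool ascertain,
              int n_chains, double heat_delta, int swap_interval,
              double seed) {
  RNG rng((uint64_t)seed);
  const int n_internal_nonroot = ntip - 3;

  std::vector<Chain> chains(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    Chain& ch = chains[c];
    ch.tr = tree_from_edge(edge, edge_len, ntip);
    ch.alpha = alpha0;
    ch.beta = 1.0 / (1.0 + heat_delta * c);
    ch.eng.init(states, as<std::vector<int>>(kchar), ncat, ascertain);
    ch.eng.set_alpha(ch.alpha);
    ch.eng.update_all(ch.tr);
    ch.eng.cache_init(ch.tr);
    ch.ll = prior_only ? 0.0 : ch.eng.loglik_cached(ch.tr);
    ch.lp = log_prior(ch.tr, ch.alpha, bl_rate, alpha_rate);
  }
  const int nnode = chains[0].tr.nnode;

  double wsum = 0.0;
  for (double w : move_weights) wsum += w;
  double w_nni = move_weights[0] / wsum,
         w_spr = move_weights[1] / wsum,
         w_bl = move_weights[2] / wsum;

  int n_samples = n_gen / sample_interval;
  List out_edge(n_samples), out_blen(n_samples);
  NumericVector out_alpha(n_samples), out_ll(n_samples), out_lp(n_samples),
      out_tl(n_samples);
  IntegerVector out_gen(n_samples);
  std::vector<long> prop(4, 0), acc(4, 0);

  TreeBackup bk;
  int cold = 0;  // chains[cold] has beta = max; we swap states, not heats,
                 // so the cold chain is always index 0
  (void)cold;

  for (int gen = 1; gen <= n_gen; ++gen) {
    for (int c = 0; c < n_chains; ++c) {
      Chain& ch = chains[c];
      Tree& tr = ch.tr;
      double u = rng.unif();
      if (u < w_nni && n_internal_nonroot > 0) {
        // --- NNI ---
        ++prop[0];
        int v;
        do { v = ntip + rng.unif_int(nnode - ntip); } while (v == tr.root);
        int p = tr.parent[v];
        int b, s;
        if (p == tr.root) {
          b = tr.child[v][rng.unif_int(2)];
          int o[2], k = 0;
          for (int i = 0; i < tr.nchild[p]; ++i)
            if (tr.child[p][i] != v) o[k++] = tr.child[p][i];
          s = o[rng.unif_int(2)];
        } else {
          b = tr.child[v][rng.unif_int(2)];
          s = (tr.child[p][0] == v) ? tr.child[p][1] : tr.child[p][0];
        }
        tr.swap_child(v, b, s);
        tr.swap_child(p, s, b);
        tr.compute_postorder();
        if (!prior_only) ch.eng.mark_path(tr, v);
        double ll2 = prior_only ? 0.0 : ch.eng.loglik_cached(tr);
        if (std::log(rng.unif() + 1e-300) < ch.beta * (ll2 - ch.ll)) {
          ch.ll = ll2;
          ++acc[0];
        } else {
          tr.swap_child(v, s, b);
          tr.swap_child(p, b, s);
          tr.compute_postorder();
          if (!prior_only) ch.eng.mark_path(tr, v);
        }
      } else if (u < w_nni + w_spr) {
        // --- SPR with uniform regraft position ---
        ++prop[1];
        // The set of valid prune nodes (everything but the root and its
        // children) has constant size, and for a fixed prune node the valid
        // regraft-edge count is invariant under the move itself, so
        // resampling each component until valid is an exactly symmetric
        // proposal.
        int i = -1, j = -1;
        for (int a = 0; a < 1000; ++a) {
          i = rng.unif_int(nnode);
          if (i != tr.root && tr.parent[i] != tr.root) break;
          i = -1;
        }
        if (i >= 0) {
          int p = tr.parent[i];
          int cs = (tr.child[p][0] == i) ? tr.child[p][1] : tr.child[p][0];
          for (int a = 0; a < 1000; ++a) {
            j = rng.unif_int(nnode);
            bool ok = (j != tr.root && j != p && j != i && j != cs);
            for (int x = j; ok && x != -1; x = tr.parent[x])
              if (x == i || x == p) ok = false;
            if (ok) break;
            j = -1;
          }
          if (j < 0) i = -1;
        }
        if (i >= 0) {
          bk.save(tr);
          int p = tr.parent[i], g = tr.parent[p];
          int cs = (tr.child[p][0] == i) ? tr.child[p][1] : tr.child[p][0];
          double t_fwd = tr.blen[j];
          double t_rev = tr.blen[cs] + tr.blen[p];
          tr.blen[cs] += tr.blen[p];
          tr.swap_child(g, p, cs);
          int q = tr.parent[j];
          double x = rng.unif() * t_fwd;
          tr.blen[p] = t_fwd - x;
          tr.blen[j] = x;
          tr.swap_child(q, j, p);
          tr.swap_child(p, cs, j);
          tr.compute_postorder();
          if (!prior_only) {
            ch.eng.update_node(tr, cs);
            ch.eng.update_node(tr, p);
            ch.eng.update_node(tr, j);
            ch.eng.mark_path(tr, p);
            ch.eng.mark_path(tr, g);
            ch.eng.mark_path(tr, q);
          }
          double ll2 = prior_only ? 0.0 : ch.eng.loglik_cached(tr);
          // total branch length is conserved, so the exponential prior is
          // unchanged; Hastings ratio from the uniform split position
          double lacc = ch.beta * (ll2 - ch.ll) + std::log(t_fwd / t_rev);
          if (std::log(rng.unif() + 1e-300) < lacc) {
            ch.ll = ll2;
            ++acc[1];
          } else {
            bk.restore(tr);
            if (!prior_only) {
              ch.eng.update_node(tr, cs);
              ch.eng.update_node(tr, p);
              ch.eng.update_node(tr, j);
              ch.eng.mark_path(tr, p);
              ch.eng.mark_path(tr, g);
              ch.eng.mark_path(tr, q);
            }
          }
        }
      } else if (u < w_nni + w_spr + w_bl) {
        // --- branch length multiplier ---
        ++prop[2];
        int v;
        do { v = rng.unif_int(nnode); } while (v == tr.root);
        double old = tr.blen[v];
        double m = std::exp(bl_lambda * (rng.unif() - 0.5));
        tr.blen[v] = old * m;
        if (!prior_only) {
          ch.eng.update_node(tr, v);
          ch.eng.mark_path(tr, tr.parent[v]);
        }
        double ll2 = prior_only ? 0.0 : ch.eng.loglik_cached(tr);
        double dlp = -bl_rate * (tr.blen[v] - old);
        double lacc = ch.beta * (ll2 - ch.ll + dlp) + std::log(m);
        if (std::log(rng.unif() + 1e-300) < lacc) {
          ch.ll = ll2;
          ch.lp += dlp;
          ++acc[2];
        } else {
          tr.blen[v] = old;
          if (!prior_only) {
            ch.eng.update_node(tr, v);
            ch.eng.mark_path(tr, tr.parent[v]);
          }
        }
      } else {
        // --- gamma shape multiplier ---
        ++prop[3];
        double old = ch.alpha;
        double m = std::exp(alpha_lambda * (rng.unif() - 0.5));
        ch.alpha = old * m;
        double ll2;
        if (prior_only) ll2 = 0.0;
        else {
          ch.eng.set_alpha(ch.alpha);
          ch.eng.update_all(tr);
          ch.eng.mark_all(tr);
          ll2 = ch.eng.loglik_cached(tr);
        }
        double dlp = -alpha_rate * (ch.alpha - old);
        double lacc = ch.beta * (ll2 - ch.ll + dlp) + std::log(m);
        if (std::log(rng.unif() + 1e-300) < lacc) {
          ch.ll = ll2;
          ch.lp += dlp;
          ++acc[3];
        } else {
          ch.alpha = old;
          if (!prior_only) {
            ch.eng.set_alpha(ch.alpha);
            ch.eng.update_all(tr);
            ch.eng.mark_all(tr);
          }
        }
      }
    }

    if (n_chains > 1 && gen % swap_interval == 0) {
      int a = rng.unif_int(n_chains - 1), b = a + 1;
      Chain& A = chains[a];
      Chain& B = chains[b];
      double lacc = (A.beta - B.beta) * ((B.ll + B.lp) - (A.ll + A.lp));
      if (std::log(rng.unif() + 1e-300) < lacc) {
        std::swap(A.tr, B.tr);
        std::swap(A.eng, B.eng);
        std::swap(A.alpha, B.alpha);
        std::swap(A.ll, B.ll);
        std::swap(A.lp, B.lp);
      }
    }

    if (gen % sample_interval == 0) {
      Chain& ch = chains[0];
      int k = gen / sample_interval - 1;
      IntegerMatrix em(ch.tr.nnode - 1, 2);
      NumericVector el(ch.tr.nnode - 1);
      tree_to_edge(ch.tr, em, el);
      out_edge[k] = em;
      out_blen[k] = el;
      out_alpha[k] = ch.alpha;
      out_ll[k] = ch.ll;
      out_lp[k] = ch.lp;
      double tl = 0.0;
      for (int v = 0; v < ch.tr.nnode; ++v)
        if (v != ch.tr.root) tl += ch.tr.blen[v];
      out_tl[k] = tl;
      out_gen[k] = gen;
    }
  }

  return List::create(
      _["edge"] = out_edge, _["blen"] = out_blen, _["alpha"] = out_alpha,
      _["logL"] = out_ll, _["log_prior"] = out_lp, _["tree_length"] = out_tl,
      _["generation"] = out_gen,
      _["proposed"] = wrap(prop), _["accepted"] = wrap(acc));
}
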