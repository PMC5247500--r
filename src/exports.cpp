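#include "tree.h"
#include "mk.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector fitch_counts_cpp(IntegerMatrix edge, int ntip,
                               IntegerMatrix states) {
  Tree tr = tree_from_edge(edge, NumericVector(0), ntip);
  std::vector<int> steps;
  fitch_counts(tr, states, steps);
  return wrap(steps);
}

// [[Rcpp::export]]
NumericVector gamma_rates_cpp(double alpha, int ncat) {
  return wrap(discrete_gamma(alpha, ncat));
}

// [[Rcpp::export]]
double mk_loglik_cpp(IntegerMatrix edge, NumericVector edge_len, int ntip,
                     IntegerMatrix states, IntegerVector kchar,
                     double alpha, int ncat, bool ascertain) {
  Tree tr = tree_from_edge(edge, edge_len, ntip);
  MkEngine eng;
  eng.init(states, as<std::vector<int>>(kchar), ncat, ascertain);
  eng.set_alpha(alpha);
  eng.update_all(tr);
  return eng.loglik(tr);
}

// Canonical non-trivial bipartitions of a tree as 0/1 strings over a
// reference taxon ordering.  `order[i]` gives the 0-based position of the
// tree's tip i+1 in the reference ordering; canonical orientation puts the
// first reference taxon on the '0' side.
// [[Rcpp::export]]
CharacterVector split_strings_cpp(IntegerMatrix edge, int ntip,
                                  IntegerVector order) {
  // handles arbitrary polytomies (consensus trees), so it does not go
  // through the binary Tree struct
  int nnode = ntip;
  for (int i = 0; i < edge.nrow(); ++i)
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(nnode);
  std::vector<bool> is_child(nnode, false);
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0) - 1].push_back(edge(i, 1) - 1);
    is_child[edge(i, 1) - 1] = true;
  }
  int root = ntip;
  for (int v = ntip; v < nnode; ++v)
    if (!is_child[v]) { root = v; break; }
  // postorder by iterative DFS
  std::vector<int> post, stack{root}, state(nnode, 0);
  while (!stack.empty()) {
    int v = stack.back();
    if (state[v] < (int)kids[v].size()) stack.push_back(kids[v][state[v]++]);
    else { post.push_back(v); stack.pop_back(); }
  }
  std::vector<std::vector<uint8_t>> in(nnode, std::vector<uint8_t>(ntip, 0));
  std::vector<std::string> out;
  for (int v : post) {
    if (v < ntip) {
      in[v][order[v]] = 1;
    } else {
      for (int w : kids[v])
        for (int t = 0; t < ntip; ++t) in[v][t] |= in[w][t];
    }
    if (v >= ntip && v != root) {
      int n1 = 0;
      for (int t = 0; t < ntip; ++t) n1 += in[v][t];
      if (n1 < 2 || n1 > ntip - 2) continue;
      std::string s(ntip, '0');
      bool flip = in[v][0] != 0;
      for (int t = 0; t < ntip; ++t)
        s[t] = (in[v][t] != 0) == flip ? '0' : '1';
      out.push_back(s);
    }
  }
  return wrap(out);
}

// Evolve nucleotide states down a tree under a reversible model given its
// spectral decomposition (P(t) = U diag(exp(lambda t)) W).  Consumes R's
// RNG stream, so results are reproducible under set.seed().
// edge must be in cladewise order (parents before children); edge_len is
// already scaled by the replicate rate; `rates` holds per-character rates.
// [[Rcpp::export]]
IntegerMatrix sim_markov_cpp(IntegerMatrix edge, NumericVector edge_len,
                             int ntip, NumericVector rates,
                             NumericMatrix U, NumericMatrix W,
                             NumericVector lambda, NumericVector pi) {
  const int nchar = rates.size();
  int nnode = ntip;
  for (int i = 0; i < edge.nrow(); ++i)
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<int> states((size_t)nnode * nchar);
  // root = parent never appearing as child
  std::vector<bool> is_child(nnode, false);
  for (int i = 0; i < edge.nrow(); ++i) is_child[edge(i, 1) - 1] = true;
  int root = ntip;
  for (int v = ntip; v < nnode; ++v)
    if (!is_child[v]) { root = v; break; }
  double cpi[4] = {pi[0], pi[0] + pi[1], pi[0] + pi[1] + pi[2], 1.0};
  for (int ch = 0; ch < nchar; ++ch) {
    double u = R::unif_rand();
    int s = 0;
    while (s < 3 && u > cpi[s]) ++s;
    states[(size_t)root * nchar + ch] = s;
  }
  for (int i = 0; i < edge.nrow(); ++i) {
    int par = edge(i, 0) - 1, chd = edge(i, 1) - 1;
    double t = edge_len[i];
    for (int ch = 0; ch < nchar; ++ch) {
      double e[4], row[4];
      double tt = t * rates[ch];
      for (int k = 0; k < 4; ++k) e[k] = std::exp(lambda[k] * tt);
      int s = states[(size_t)par * nchar + ch];
      double tot = 0.0;
      for (int j = 0; j < 4; ++j) {
        double p = 0.0;
        for (int k = 0; k < 4; ++k) p += U(s, k) * e[k] * W(k, j);
        row[j] = p > 0 ? p : 0;
        tot += row[j];
      }
      double u = R::unif_rand() * tot;
      double acc = 0.0;
      int out = 3;
      for (int j = 0; j < 4; ++j) {
        acc += row[j];
        if (u <= acc) { out = j; break; }
      }
      states[(size_t)chd * nchar + ch] = out;
    }
  }
  IntegerMatrix res(ntip, nchar);
  for (int v = 0; v < ntip; ++v)
    for (int ch = 0; ch < nchar; ++ch)
      res(v, ch) = states[(size_t)v * nchar + ch] + 1;
  return res;
}

// Stateful likelihood context for the ML search: the engine (patterns
// compressed once) holds the current tree and cached per-node conditional
// likelihoods, so a single-branch update only recomputes the path to the
// root.
struct MlCtx {
  Tree tr;
  MkEngine eng;
  double alpha = 1.0;
};

// [[Rcpp::export]]
SEXP ml_ctx_new(IntegerMatrix states, IntegerVector kchar, int ncat,
                bool ascertain) {
  MlCtx* ctx = new MlCtx();
  ctx->eng.init(states, as<std::vector<int>>(kchar), ncat, ascertain);
  return XPtr<MlCtx>(ctx, true);
}

// [[Rcpp::export]]
double ml_ctx_set_tree(SEXP ptr, IntegerMatrix edge, NumericVector edge_len,
                       int ntip, double alpha) {
  XPtr<MlCtx> ctx(ptr);
  ctx->tr = tree_from_edge(edge, edge_len, ntip);
  ctx->alpha = alpha;
  ctx->eng.set_alpha(alpha);
  ctx->eng.update_all(ctx->tr);
  ctx->eng.cache_init(ctx->tr);
  return ctx->eng.loglik_cached(ctx->tr);
}

// set the length of the edge above node `child` (1-based ape node id in the
// edge matrix passed to ml_ctx_set_tree) and return the new log-likelihood
// [[Rcpp::export]]
double ml_ctx_set_length(SEXP ptr, int child, double len) {
  XPtr<MlCtx> ctx(ptr);
  int v = child - 1;
  ctx->tr.blen[v] = len;
  ctx->eng.update_node(ctx->tr, v);
  ctx->eng.mark_path(ctx->tr, ctx->tr.parent[v]);
  return ctx->eng.loglik_cached(ctx->tr);
}

// [[Rcpp::export]]
double ml_ctx_set_alpha(SEXP ptr, double alpha) {
  XPtr<MlCtx> ctx(ptr);
  ctx->alpha = alpha;
  ctx->eng.set_alpha(alpha);
  ctx->eng.update_all(ctx->tr);
  ctx->eng.mark_all(ctx->tr);
  return ctx->eng.loglik_cached(ctx->tr);
}

// [[Rcpp::export]]
NumericVector ml_ctx_lengths(SEXP ptr, IntegerMatrix edge) {
  XPtr<MlCtx> ctx(ptr);
  NumericVector out(edge.nrow());
  for (int i = 0; i < edge.nrow(); ++i)
    out[i] = ctx->tr.blen[edge(i, 1) - 1];
  return out;
}
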