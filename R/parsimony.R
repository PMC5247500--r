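#' Parsimony search configuration
#'
#' @param weighting `"equal"` (tree score = total Fitch steps) or `"implied"`
#'   (Goloboff fit, down-weighting homoplastic characters).
#' @param k implied-weighting concavity constant (> 0).
#' @param n_random_starts random addition-sequence starting trees.
#' @param move_set `"NNI"` or `"SPR"` (SPR adds random SPR improvement
#'   attempts on top of the NNI sweeps).
#' @param max_rounds hill-climbing rounds per start.
#' @param spr_per_round random SPR attempts per round when `move_set="SPR"`.
#' @param max_trees cap on retained tied-best topologies.
#' @param plateau_steps random equal-score NNI walk steps used to sample the
#'   plateau of tied optima feeding the consensus (0 disables).
#' @param seed RNG seed for the search.
#' @return an object of class `parsimony_config`.
#' @export
parsimony_config <- function(weighting = c("equal", "implied"), k = 2,
                             n_random_starts = 10, move_set = c("NNI", "SPR"),
                             max_rounds = 100, spr_per_round = 200,
                             max_trees = 500, plateau_steps = 200, seed = 1) {
  weighting <- match.arg(weighting)
  move_set <- match.arg(move_set)
  stopifnot(k > 0, n_random_starts >= 1)
  structure(list(weighting = weighting, k = k,
                 n_random_starts = as.integer(n_random_starts),
                 move_set = move_set, max_rounds = as.integer(max_rounds),
                 spr_per_round = as.integer(spr_per_round),
                 max_trees = as.integer(max_trees),
                 plateau_steps = as.integer(plateau_steps), seed = seed),
            class = "parsimony_config")
}

#' Equal-weights parsimony score
#'
#' Total Fitch step count of the matrix on the tree (to minimize).  Invariant
#' under re-rooting.
#'
#' @param x a [morpho_matrix].
#' @param tree a `phylo` on the same taxa.
#' @return integer score.
#' @export
ew_score <- function(x, tree) {
  sum(fitch_steps(x, tree))
}

#' Implied-weights parsimony fit
#'
#' Goloboff fit `F = sum_i k / (k + e_i)` with extra steps
#' `e_i = s_i - m_i`, to MAXIMIZE; a search maximizing `F` equivalently
#' minimizes `sum_i e_i / (e_i + k)`.
#'
#' @inheritParams ew_score
#' @param k concavity constant (> 0).
#' @return the fit (higher is better).
#' @export
iw_score <- function(x, tree, k = 2) {
  stopifnot(k > 0)
  s <- fitch_steps(x, tree)
  e <- s - (x$n_states - 1L)
  sum(k / (k + e))
}

#' Heuristic parsimony tree search
#'
#' Random addition-sequence starting trees followed by steepest-ascent
#' hill-climbing (NNI sweeps, optionally with random SPR improvement
#' attempts).  All distinct topologies tying the best score found across
#' starts are retained (up to `max_trees`) so that a majority-rule consensus
#' of the optimal set can be taken.
#'
#' @param x a [morpho_matrix] with >= 4 taxa.
#' @param config a [parsimony_config()].
#' @return list with `best_score` (steps for EW, fit for IW), `best_trees`
#'   (a `multiPhylo` of tied optima) and `n_evaluated`.
#' @export
parsimony_search <- function(x, config = parsimony_config()) {
  taxa <- x$taxa
  if (length(taxa) < 4) stop("parsimony search needs at least 4 taxa")
  k_iw <- if (config$weighting == "implied") config$k else -1
  res <- parsimony_search_cpp(
    x$states, as.integer(x$n_states - 1L), k_iw,
    config$n_random_starts, config$max_rounds,
    config$move_set == "SPR", config$spr_per_round, config$max_trees,
    config$plateau_steps, as.double(config$seed))
  trees <- lapply(res$trees, edge_to_phylo, taxa = taxa)
  class(trees) <- "multiPhylo"
  best_score <- if (config$weighting == "equal") {
    as.integer(round(res$cost))
  } else {
    length(x$char_type) - res$cost   # fit F = N - sum e/(e+k)
  }
  list(best_score = best_score, best_trees = trees,
       n_evaluated = res$n_evaluated)
}

# phylo from a (preorder, 1-based) edge matrix produced by the C++ engines
edge_to_phylo <- function(edge, taxa, edge_length = NULL) {
  tr <- list(edge = edge, Nnode = max(edge) - length(taxa),
             tip.label = taxa)
  if (!is.null(edge_length)) tr$edge.length <- edge_length
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}
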