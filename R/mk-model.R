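#' Mk likelihood configuration
#'
#' @param n_gamma_categories number of discretized gamma rate categories.
#' @param ascertainment `"none"` for the plain Mk model or `"variable"` for
#'   the Mkv conditional likelihood, which corrects for matrices that omit
#'   invariant characters.
#' @param state_count_rule `"observed"` sets each character's state count to
#'   the number of distinct states observed (floored at 2); `"by_type"` fixes
#'   it at 2 for binary and 4 for multistate characters.
#' @param tol optimizer convergence tolerance on the log-likelihood.
#' @param max_nni_rounds topology improvement rounds in [ml_search()].
#' @return an object of class `mk_config`.
#' @export
mk_config <- function(n_gamma_categories = 4,
                      ascertainment = c("none", "variable"),
                      state_count_rule = c("observed", "by_type"),
                      tol = 1e-4, max_nni_rounds = 20) {
  stopifnot(n_gamma_categories >= 1)
  structure(list(n_gamma_categories = as.integer(n_gamma_categories),
                 ascertainment = match.arg(ascertainment),
                 state_count_rule = match.arg(state_count_rule),
                 tol = tol, max_nni_rounds = as.integer(max_nni_rounds)),
            class = "mk_config")
}

#' Mk transition probability matrix
#'
#' Equal-rates k-state matrix normalized to one expected change per unit
#' branch length: with `tau = t * rate`,
#' `P_same = 1/k + (k-1)/k * exp(-k*tau/(k-1))` and
#' `P_diff = (1/k) * (1 - exp(-k*tau/(k-1)))`.
#'
#' @param t branch length (>= 0).
#' @param k_states number of states (>= 2).
#' @param rate rate multiplier.
#' @return k x k stochastic matrix.
#' @export
mk_transition <- function(t, k_states = 2, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  stopifnot(k_states >= 2)
  k <- k_states
  tau <- t * rate
  e <- exp(-k * tau / (k - 1))
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

#' Discretized gamma rate categories
#'
#' Mean rates of `n_cat` equal-probability slices of the
#' `Gamma(shape = alpha, rate = alpha)` distribution (mean 1), the standard
#' discretization for among-character rate heterogeneity.
#'
#' @param alpha gamma shape (> 0).
#' @param n_cat number of categories.
#' @return numeric vector of rates with mean 1.
#' @export
gamma_categories <- function(alpha, n_cat = 4) {
  stopifnot(alpha > 0, n_cat >= 1)
  gamma_rates_cpp(alpha, as.integer(n_cat))
}

# recode each character's states to 0..k-1 ranks and attach the per-character
# state count under the configured rule
mk_state_data <- function(x, config) {
  st <- x$states
  kchar <- integer(ncol(st))
  for (j in seq_len(ncol(st))) {
    obs <- sort(unique(st[, j]))
    st[, j] <- match(st[, j], obs) - 1L
    kchar[j] <- max(2L, length(obs))
  }
  if (config$state_count_rule == "by_type") {
    kchar <- ifelse(x$char_type == "binary", 2L, 4L)
    st <- x$states  # original coding already lies within 0..k-1
  }
  list(states = st, kchar = as.integer(kchar))
}

#' Mk(+Gamma, +Mkv) log-likelihood
#'
#' Felsenstein pruning per character with uniform root frequencies `1/k`,
#' averaged over the discretized gamma categories.  With
#' `ascertainment = "variable"` each character's likelihood is divided by the
#' probability of being variable for its state count (Mkv conditional
#' likelihood).
#'
#' @param x a [morpho_matrix].
#' @param tree a `phylo` with branch lengths on the taxa of `x`.
#' @param alpha gamma shape.
#' @param config an [mk_config()].
#' @return log-likelihood (finite for valid inputs).
#' @export
mk_loglik <- function(x, tree, alpha = 1, config = mk_config()) {
  idx <- match(tree$tip.label, x$taxa)
  if (anyNA(idx)) stop("leaf missing from matrix")
  sd <- mk_state_data(x, config)
  tree <- ape::reorder.phylo(tree, "postorder")
  mk_loglik_cpp(tree$edge, tree$edge.length, length(tree$tip.label),
                sd$states[idx, , drop = FALSE], sd$kchar, alpha,
                config$n_gamma_categories,
                config$ascertainment == "variable")
}

# NNI neighbours of an internal edge of an (unrooted-style) phylo, produced
# by reassigning parents so branch lengths stay with their child subtree
nni_neighbours <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  internal <- which(edge[, 2] > ntip)
  root <- ntip + 1
  out <- list()
  for (ei in internal) {
    u <- edge[ei, 1]
    v <- edge[ei, 2]
    vkids <- which(edge[, 1] == v)
    ukids <- setdiff(which(edge[, 1] == u), ei)
    pairs <- if (u == root || length(ukids) > 1) {
      lapply(ukids, function(ci) c(vkids[1], ci))
    } else {
      lapply(vkids, function(bi) c(bi, ukids[1]))
    }
    for (p in pairs) {
      e2 <- edge
      e2[p[1], 1] <- u
      e2[p[2], 1] <- v
      t2 <- tree
      t2$edge <- e2
      attr(t2, "order") <- NULL
      attr(t2, "central") <- v          # child node id of the swapped edge
      out[[length(out) + 1]] <- t2
    }
  }
  out
}

#' Maximum-likelihood tree search under Mk+Gamma
#'
#' Alternates numerical optimization of branch lengths and the gamma shape
#' (quasi-Newton on log scale) with steepest-ascent NNI rounds from a
#' neighbour-joining starting tree on Hamming distances.  Maximum likelihood
#' returns a single fully resolved tree, which also serves as its own
#' "consensus".
#'
#' @param x a [morpho_matrix] with >= 4 taxa.
#' @param config an [mk_config()].
#' @param seed RNG seed (used only to break ties deterministically).
#' @param start_tree optional starting `phylo`; defaults to NJ on Hamming
#'   distances.
#' @return list with `tree` (branch lengths optimized), `alpha` and `logL`.
#' @export
ml_search <- function(x, config = mk_config(), seed = 1, start_tree = NULL) {
  taxa <- x$taxa
  if (length(taxa) < 4) stop("ML search needs at least 4 taxa")
  set.seed(seed)
  if (is.null(start_tree)) {
    st <- x$states
    n <- nrow(st)
    D <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- max(mean(st[i, ] != st[j, ]), 1e-4)
    }
    start_tree <- ape::nj(as.dist(D))
  }
  tree <- ape::unroot(start_tree)
  tree$edge.length <- pmax(tree$edge.length, 1e-4)
  sd <- mk_state_data(x, config)
  asc <- config$ascertainment == "variable"
  ncat <- config$n_gamma_categories
  # tip numbering is fixed for the whole search; one stateful context holds
  # the compressed patterns and cached per-node conditional likelihoods, so
  # a single-branch update only recomputes the path to the root
  ord <- match(tree$tip.label, taxa)
  ctx <- ml_ctx_new(sd$states[ord, , drop = FALSE], sd$kchar, ncat, asc)
  lo <- log(1e-7)
  hi <- log(50)

  # coordinate-wise optimization: Brent per branch on log scale, then the
  # gamma shape, swept until the log-likelihood stalls
  # one full coordinate-descent pass from given starting lengths
  sweep_fit <- function(tr, lengths, alpha) {
    n_tip <- length(taxa)
    ll <- ml_ctx_set_tree(ctx, tr$edge, lengths, n_tip, alpha)
    children <- tr$edge[, 2]
    for (sweep in 1:20) {
      prev <- ll
      for (ci in children) {
        opt <- optimize(function(lg) ml_ctx_set_length(ctx, ci, exp(lg)),
                        c(lo, hi), maximum = TRUE, tol = 1e-3)
        ll <- ml_ctx_set_length(ctx, ci, exp(opt$maximum))
      }
      aopt <- optimize(function(lg) ml_ctx_set_alpha(ctx, exp(lg)),
                       c(log(1e-3), log(50)), maximum = TRUE, tol = 1e-3)
      alpha <- exp(aopt$maximum)
      ll <- ml_ctx_set_alpha(ctx, alpha)
      if (ll - prev < max(config$tol, 1e-3)) break
    }
    list(lengths = ml_ctx_lengths(ctx, tr$edge), alpha = alpha, logL = ll)
  }

  optimise_lengths <- function(tr, alpha, multistart = FALSE) {
    tr <- ape::reorder.phylo(tr, "postorder")
    starts <- list(list(tr$edge.length, alpha))
    if (multistart) {
      # flat-length and neutral-shape restarts guard against local optima
      # in the joint (lengths, alpha) surface of small noisy matrices
      for (l0 in list(rep(0.2, nrow(tr$edge)), rep(0.05, nrow(tr$edge)))) {
        for (a0 in unique(c(alpha, 1))) {
          starts <- c(starts, list(list(l0, a0)))
        }
      }
    }
    best <- NULL
    for (s0 in starts) {
      cand <- sweep_fit(tr, s0[[1]], s0[[2]])
      if (is.null(best) || cand$logL > best$logL) best <- cand
    }
    tr$edge.length <- best$lengths
    list(tree = tr, alpha = best$alpha, logL = best$logL)
  }

  # score a neighbour after re-optimizing the length of its central edge
  neighbour_loglik <- function(tr, alpha, central) {
    ci <- central                     # stable node id of the swapped edge
    tr <- ape::reorder.phylo(tr, "postorder")
    ml_ctx_set_tree(ctx, tr$edge, tr$edge.length, length(taxa), alpha)
    opt <- optimize(function(lg) ml_ctx_set_length(ctx, ci, exp(lg)),
                    c(lo, hi), maximum = TRUE, tol = 1e-3)
    ml_ctx_set_length(ctx, ci, exp(opt$maximum))
  }

  fit <- optimise_lengths(tree, 1, multistart = TRUE)
  moved <- FALSE
  for (round in seq_len(config$max_nni_rounds)) {
    nb <- nni_neighbours(fit$tree)
    ll <- vapply(nb, function(t2) {
      neighbour_loglik(t2, fit$alpha, attr(t2, "central"))
    }, 0)
    if (!length(ll) || max(ll) <= fit$logL + config$tol) break
    best <- nb[[which.max(ll)]]
    fit <- optimise_lengths(best, fit$alpha)
    moved <- TRUE
  }
  if (moved) fit <- optimise_lengths(fit$tree, fit$alpha, multistart = TRUE)
  list(tree = fit$tree, alpha = fit$alpha, logL = fit$logL)
}
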