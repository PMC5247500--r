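#' Fitch parsimony steps per character
#'
#' Minimum number of state changes on `tree` under unordered (Fitch)
#' parsimony, computed per character by the standard bottom-up pass.
#'
#' @param x a [morpho_matrix], or a named vector of states for a single
#'   character.
#' @param tree a `phylo` whose leaf set matches the taxa of `x`.
#' @return integer vector of step counts (one per character).
#' @export
fitch_steps <- function(x, tree) {
  if (!is.matrix(x) && !inherits(x, "morpho_matrix")) {
    x <- matrix(as.integer(x), ncol = 1, dimnames = list(names(x), NULL))
  }
  st <- if (inherits(x, "morpho_matrix")) x$states else x
  if (is.null(rownames(st))) stop("character states must be named by taxon")
  idx <- match(tree$tip.label, rownames(st))
  if (anyNA(idx)) {
    stop("leaf missing from matrix: ",
         paste(setdiff(tree$tip.label, rownames(st)), collapse = ", "))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  fitch_counts_cpp(tree$edge, length(tree$tip.label),
                   st[idx, , drop = FALSE])
}

#' Consistency index of a matrix on a tree
#'
#' `CI = sum(m_i) / sum(s_i)` over the variable characters, where `s_i` is
#' the Fitch step count of character `i` on `tree` and
#' `m_i = observed states - 1` is its minimum conceivable number of changes.
#' Invariant characters (`s_i = 0`) contribute to neither sum.
#'
#' @param x a [morpho_matrix].
#' @param tree reference tree.
#' @return CI in (0, 1].
#' @export
consistency_index <- function(x, tree) {
  s <- fitch_steps(x, tree)
  m <- x$n_states - 1L
  keep <- s > 0L
  if (!any(keep)) stop("CI undefined: all characters invariant on the tree")
  sum(m[keep]) / sum(s[keep])
}

#' Target homoplasy profile for rejection sampling
#'
#' Consistency-index bins of width 0.05 spanning the empirical bounds
#' `[0.26, 1.0]` (the final bin, `[0.96, 1.0]`, is closed and slightly
#' narrower), with a target proportion of matrices per bin.
#'
#' The default proportions are a documented stand-in for the empirical
#' distribution of CI in published morphological matrices: a triangular
#' density peaking near CI = 0.6.  Users reproducing a specific empirical
#' profile should supply their own `proportions`.
#'
#' @param bin_edges increasing CI bin edges from 0.26 to 1.0.
#' @param proportions non-negative target fractions per bin; normalized to
#'   sum to 1.
#' @return an object of class `homoplasy_target`.
#' @export
homoplasy_target <- function(bin_edges = c(seq(0.26, 0.96, by = 0.05), 1.0),
                             proportions = NULL) {
  stopifnot(all(diff(bin_edges) > 0),
            abs(bin_edges[1] - 0.26) < 1e-9,
            abs(bin_edges[length(bin_edges)] - 1.0) < 1e-9)
  n_bin <- length(bin_edges) - 1
  if (is.null(proportions)) {
    mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
    peak <- 0.6
    proportions <- ifelse(mid <= peak, (mid - 0.26) / (peak - 0.26),
                          (1.0 - mid) / (1.0 - peak))
    proportions <- pmax(proportions, 0.02)
  }
  stopifnot(length(proportions) == n_bin, all(proportions >= 0),
            sum(proportions) > 0)
  structure(list(bin_edges = bin_edges,
                 proportions = proportions / sum(proportions)),
            class = "homoplasy_target")
}

#' @export
print.homoplasy_target <- function(x, ...) {
  cat("homoplasy target:", length(x$proportions), "CI bins on [0.26, 1]\n")
  invisible(x)
}

# bin index for a CI value, or NA when outside [0.26, 1]; bins are [lo, hi)
# except the final closed bin
ci_bin <- function(ci, target) {
  edges <- target$bin_edges
  n_bin <- length(edges) - 1
  if (is.na(ci) || ci < edges[1] || ci > edges[n_bin + 1]) return(NA_integer_)
  b <- findInterval(ci, edges, rightmost.closed = TRUE)
  min(b, n_bin)
}

# largest-remainder apportionment of n_total over the target proportions
bin_quotas <- function(target, n_total) {
  raw <- target$proportions * n_total
  q <- floor(raw)
  short <- n_total - sum(q)
  if (short > 0) {
    extra <- order(raw - q, decreasing = TRUE)[seq_len(short)]
    q[extra] <- q[extra] + 1
  }
  as.integer(q)
}

#' Replicate-matrix generator for the rejection sampler
#'
#' Returns a closure that, given a seed, draws fresh replicate parameters
#' (gamma shape and substitution rate i.i.d. Exponential(mean 1)), simulates
#' a matrix on `tree` and scores its consistency index on the generating
#' tree.
#'
#' @param tree generating tree (with branch lengths).
#' @param n_characters matrix width.
#' @param binary_fraction proportion of binary characters.
#' @return function `(seed) -> list(matrix, ci, params)`.
#' @export
matrix_generator <- function(tree, n_characters = 100,
                             binary_fraction = 0.55) {
  force(tree)
  function(seed) {
    params <- draw_replicate_params(seed, n_characters, binary_fraction)
    m <- simulate_matrix(tree, params)
    ci <- tryCatch(consistency_index(m, tree), error = function(e) NA_real_)
    list(matrix = m, ci = ci, params = params)
  }
}

#' Homoplasy-calibrated rejection sampling of matrices
#'
#' Repeatedly draws fresh replicate matrices (new substitution parameters
#' each draw), bins each matrix by its consistency index on the generating
#' tree, and accepts it only while its bin's quota is unfilled.  Matrices
#' with CI outside `[0.26, 1.0]` are always discarded.  Stops when every
#' quota is filled, so the accepted CI histogram equals the quota vector
#' exactly.
#'
#' @param generator a callable `(seed) -> list(matrix, ci, ...)`, e.g. from
#'   [matrix_generator()].
#' @param target a [homoplasy_target()].
#' @param n_total number of matrices to accept.
#' @param seed master seed; attempt seeds are derived deterministically.
#' @param max_attempts guard against unfillable bins.
#' @param log_file optional CSV path logging
#'   `(attempt, seed, ci, bin, accepted)` per draw.
#' @return list with `matrices`, `ci`, `bin`, `params` (per accepted matrix,
#'   in acceptance order), `quotas` and `n_attempts`.
#' @export
bin_match_sampler <- function(generator, target = homoplasy_target(),
                              n_total = 100, seed = 1,
                              max_attempts = 1000 * n_total,
                              log_file = NULL) {
  quotas <- bin_quotas(target, n_total)
  filled <- integer(length(quotas))
  accepted <- vector("list", n_total)
  ci_out <- numeric(n_total)
  bin_out <- integer(n_total)
  par_out <- vector("list", n_total)
  n_acc <- 0L
  attempt <- 0L
  log_rows <- if (!is.null(log_file)) vector("list", 0) else NULL
  while (n_acc < n_total) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      short <- paste(sprintf("bin %d: %d/%d", which(filled < quotas),
                             filled[filled < quotas],
                             quotas[filled < quotas]), collapse = "; ")
      stop("bin_match_sampler: max_attempts exceeded; unfilled quotas: ",
           short)
    }
    attempt_seed <- (seed * 48271 + attempt * 16807) %% 2147483647
    draw <- generator(attempt_seed)
    b <- ci_bin(draw$ci, target)
    ok <- !is.na(b) && filled[b] < quotas[b]
    if (ok) {
      filled[b] <- filled[b] + 1L
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- draw$matrix
      ci_out[n_acc] <- draw$ci
      bin_out[n_acc] <- b
      par_out[[n_acc]] <- draw$params
    }
    if (!is.null(log_file)) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(attempt = attempt, seed = attempt_seed, ci = draw$ci,
                   bin = ifelse(is.na(b), NA_integer_, b), accepted = ok)
    }
  }
  if (!is.null(log_file)) {
    write.csv(do.call(rbind, log_rows), log_file, row.names = FALSE)
  }
  list(matrices = accepted, ci = ci_out, bin = bin_out, params = par_out,
       quotas = quotas, n_attempts = attempt)
}
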