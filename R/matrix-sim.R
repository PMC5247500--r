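#' Simulation parameters for one replicate matrix
#'
#' Bundles the generating-model knobs: HKY transition/transversion ratio
#' `kappa`, stationary frequencies `pi` (A, C, G, T order), gamma shape
#' `alpha` for among-character rate heterogeneity (continuous, shape = rate so
#' the mean rate is 1), the replicate-level substitution rate `mu` that scales
#' every branch, the matrix width and the binary:multistate proportion.
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param pi stationary frequencies over the four nucleotide states; must be
#'   positive and sum to 1.
#' @param alpha gamma shape (> 0) for per-character rates.
#' @param mu replicate substitution rate (> 0); multiplies all branch lengths.
#' @param n_characters matrix width.
#' @param binary_fraction proportion of characters recoded to binary (R/Y).
#' @param seed optional RNG seed recorded with the parameters.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(kappa = 2, pi = c(0.2, 0.2, 0.3, 0.3), alpha = 1,
                       mu = 1, n_characters = 100, binary_fraction = 0.55,
                       seed = NULL) {
  stopifnot(length(pi) == 4, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            kappa > 0, alpha > 0, mu > 0,
            binary_fraction >= 0, binary_fraction <= 1, n_characters >= 1)
  structure(list(kappa = kappa, pi = pi, alpha = alpha, mu = mu,
                 n_characters = as.integer(n_characters),
                 binary_fraction = binary_fraction, seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "HKY+G simulation parameters: kappa=%.3g alpha=%.4g mu=%.4g\n", x$kappa,
    x$alpha, x$mu))
  cat(sprintf("  pi = [%s]; %d characters, %.0f%% binary\n",
              paste(x$pi, collapse = ", "), x$n_characters,
              100 * x$binary_fraction))
  invisible(x)
}

#' Draw per-replicate substitution parameters
#'
#' The gamma shape and the replicate substitution rate are drawn i.i.d. from
#' exponential distributions with mean 1; `kappa` is fixed at 2 and `pi` at
#' (0.2, 0.2, 0.3, 0.3).
#'
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @inheritParams sim_params
#' @return a [sim_params] object.
#' @export
draw_replicate_params <- function(seed = NULL, n_characters = 100,
                                  binary_fraction = 0.55) {
  if (!is.null(seed)) set.seed(seed)
  draws <- rexp(2, rate = 1)
  sim_params(alpha = draws[1], mu = draws[2], n_characters = n_characters,
             binary_fraction = binary_fraction, seed = seed)
}

# HKY rate matrix (A,C,G,T), normalized so the expected substitution rate at
# stationarity is 1, together with its spectral decomposition (symmetrized
# through the stationary distribution, so eigenvalues are real).
hky_decomposition <- function(params) {
  pi <- params$pi
  kappa <- params$kappa
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  transitions <- rbind(c(1, 3), c(2, 4))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- any(apply(transitions, 1, function(p) all(sort(c(i, j)) == p)))
    Q[i, j] <- if (ti) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(Q = Q,
       values = eig$values,
       U = diag(1 / sq) %*% eig$vectors,        # right transform
       W = t(eig$vectors) %*% diag(sq))         # left transform
}

#' HKY transition probability matrix
#'
#' `P(t * rate)` from the HKY rate matrix normalized to one expected
#' substitution per unit branch length at stationarity.
#'
#' @param t branch length (>= 0), expected substitutions per character.
#' @param rate per-character rate multiplier (>= 0).
#' @param params a [sim_params] object supplying `kappa` and `pi`.
#' @return a 4x4 stochastic matrix (rows A, C, G, T).
#' @export
hky_transition_matrix <- function(t, rate = 1, params = sim_params()) {
  if (t < 0) stop("branch length must be non-negative")
  if (rate < 0) stop("rate must be non-negative")
  dec <- hky_decomposition(params)
  P <- dec$U %*% diag(exp(dec$values * t * rate)) %*% dec$W
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(dec$Q)
  P
}

#' Simulate nucleotide characters along a tree
#'
#' For each character a rate `r ~ Gamma(shape = alpha, rate = alpha)`
#' (continuous, mean 1) is drawn, the root state is drawn from `pi`, and the
#' state evolves along every edge with the HKY transition matrix of length
#' `edge_length * mu * r`.
#'
#' @param tree a `phylo` with branch lengths.
#' @param params a [sim_params] object.
#' @param n_characters number of characters to simulate.
#' @param seed RNG seed (deterministic output given `(tree, params, seed)`).
#' @return integer matrix (taxa x characters) of states 1..4 = A,C,G,T, with
#'   the per-character rates in attribute `"rates"`.
#' @export
simulate_nucleotides <- function(tree, params,
                                 n_characters = params$n_characters,
                                 seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  dec <- hky_decomposition(params)
  rates <- rgamma(n_characters, shape = params$alpha, rate = params$alpha)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  res <- sim_markov_cpp(tree$edge, tree$edge.length * params$mu,
                        length(tree$tip.label), rates, dec$U, dec$W,
                        dec$values, params$pi)
  rownames(res) <- tree$tip.label
  attr(res, "rates") <- rates
  res
}

#' A discrete character matrix
#'
#' Container for a taxa-by-characters table of small non-negative integer
#' states with a per-character type (binary or multistate).
#'
#' @param states integer matrix with taxa as (named) rows; binary columns must
#'   be within \{0,1\} and multistate columns within \{0,1,2,3\}.
#' @param char_type character vector, `"binary"` or `"multistate"`, one per
#'   column.
#' @return an object of class `morpho_matrix` with elements `states`,
#'   `char_type`, `n_states` (observed state count per character) and `taxa`.
#' @export
morpho_matrix <- function(states, char_type) {
  stopifnot(is.matrix(states), !is.null(rownames(states)),
            length(char_type) == ncol(states),
            all(char_type %in% c("binary", "multistate")))
  storage.mode(states) <- "integer"
  if (anyNA(states) || any(states < 0L) || any(states > 3L)) {
    stop("states must be integers in 0..3 with no missing data")
  }
  if (any(states[, char_type == "binary", drop = FALSE] > 1L)) {
    stop("binary characters must only contain states 0 and 1")
  }
  n_states <- apply(states, 2, function(x) length(unique(x)))
  structure(list(states = states, char_type = char_type,
                 n_states = as.integer(n_states), taxa = rownames(states)),
            class = "morpho_matrix")
}

#' @export
print.morpho_matrix <- function(x, ...) {
  cat(sprintf("morpho_matrix: %d taxa x %d characters (%d binary, %d multistate)\n",
              nrow(x$states), ncol(x$states), sum(x$char_type == "binary"),
              sum(x$char_type == "multistate")))
  invisible(x)
}

#' @export
dim.morpho_matrix <- function(x) dim(x$states)

#' Recode nucleotide characters as morphological characters
#'
#' A random `round(binary_fraction * N)` of the columns (ties rounded up) are
#' recoded purine/pyrimidine (A,G -> 0; C,T -> 1); the remaining columns map
#' A,C,G,T -> 0,1,2,3.
#'
#' @param nucleotides taxa x characters matrix of states 1..4 (A,C,G,T), as
#'   produced by [simulate_nucleotides()].
#' @param binary_fraction proportion of binary characters.
#' @param seed RNG seed governing which columns become binary.
#' @return a [morpho_matrix]; the source nucleotides are kept in attribute
#'   `"nucleotides"`.
#' @export
recode_characters <- function(nucleotides, binary_fraction = 0.55,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_char <- ncol(nucleotides)
  n_bin <- as.integer(floor(binary_fraction * n_char + 0.5))
  bin_cols <- sort(sample.int(n_char, n_bin))
  states <- nucleotides - 1L            # A,C,G,T -> 0,1,2,3
  attr(states, "rates") <- NULL
  ry <- c(0L, 1L, 0L, 1L)               # A,G purines; C,T pyrimidines
  states[, bin_cols] <- ry[nucleotides[, bin_cols]]
  char_type <- rep("multistate", n_char)
  char_type[bin_cols] <- "binary"
  out <- morpho_matrix(states, char_type)
  attr(out, "nucleotides") <- nucleotides
  out
}

#' Simulate one morphological matrix
#'
#' Convenience wrapper: [simulate_nucleotides()] followed by
#' [recode_characters()], all driven by one [sim_params] object.
#'
#' @inheritParams simulate_nucleotides
#' @param seed RNG seed for both steps.
#' @return a [morpho_matrix].
#' @export
simulate_matrix <- function(tree, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nuc <- simulate_nucleotides(tree, params)
  recode_characters(nuc, params$binary_fraction)
}
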