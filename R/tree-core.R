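#' Fully balanced generating tree
#'
#' Builds the fully symmetric rooted binary tree used as one of the two
#' generating topologies: every internal node has two children and all leaves
#' sit at depth `log2(n_leaves)`.  Leaves are labelled `t1..tn` left to right
#' so replicates are comparable.
#'
#' Both generating trees are ultrametric with root-to-tip height `height`
#' (expected substitutions per character before the replicate rate is
#' applied), with speciation events evenly spaced in time.  Ultrametry is
#' what makes the pectinate tree hard: its deep internodes are short relative
#' to the long pendant branches, so deep clades carry little signal.
#'
#' @param n_leaves number of leaves; must be a power of two (>= 4).
#' @param height root-to-tip path length; the per-replicate substitution rate
#'   multiplies this at simulation time.
#' @return a rooted ultrametric `phylo` object.
#' @seealso [make_asymmetric_tree()], [assign_branch_lengths()]
#' @export
#' @examples
#' tr <- make_symmetric_tree(8)
#' ape::Ntip(tr)
make_symmetric_tree <- function(n_leaves, height = 1) {
  if (length(n_leaves) != 1 || n_leaves < 4 ||
      bitwAnd(as.integer(n_leaves), as.integer(n_leaves) - 1L) != 0L) {
    stop("symmetric tree requires 2^k leaves")
  }
  if (height <= 0) stop("height must be positive")
  tr <- ape::stree(n_leaves, type = "balanced")
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr$edge.length <- rep(height / log2(n_leaves), nrow(tr$edge))
  tr
}

#' Fully pectinate generating tree
#'
#' Builds the fully asymmetric (ladder / caterpillar) rooted tree: each
#' internal node subtends one leaf except the deepest cherry, so leaf `t1`
#' sits at topological depth `n_leaves - 1`.  The tree is ultrametric
#' (see [make_symmetric_tree()]) with the `n_leaves - 1` splits evenly
#' spaced between the root and the tips.
#'
#' @inheritParams make_symmetric_tree
#' @param n_leaves number of leaves (>= 3).
#' @return a rooted ultrametric `phylo` object.
#' @export
make_asymmetric_tree <- function(n_leaves, height = 1) {
  if (length(n_leaves) != 1 || n_leaves < 3) {
    stop("asymmetric tree requires at least 3 leaves")
  }
  if (height <= 0) stop("height must be positive")
  # ((((t1,t2),t3),t4)...,tn); split k (from the root, k = 1..n-1) happens
  # at time (k-1)/(n-1), tips at time 1
  n <- n_leaves
  step <- height / (n - 1)
  txt <- sprintf("(t1:%.12g,t2:%.12g)", step, step)
  for (i in seq(3, n)) {
    pend <- (i - 1) * step          # leaf t_i diverged (i - 1) steps ago
    txt <- sprintf("(%s:%.12g,t%d:%.12g)", txt, step, i, pend)
  }
  ape::read.tree(text = paste0(txt, ";"))
}

#' Assign branch lengths to a tree
#'
#' @param tree a `phylo` object.
#' @param scheme `"unit"` sets every base length to 1; `"custom"` takes base
#'   lengths from `lengths` (one per edge, in `tree$edge` order).
#' @param rate_multiplier positive scalar multiplying every base length.
#' @param lengths base edge lengths for `scheme = "custom"`.
#' @return the tree with `edge.length` set.
#' @export
assign_branch_lengths <- function(tree, scheme = c("unit", "custom"),
                                  rate_multiplier = 1, lengths = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(rate_multiplier) || rate_multiplier <= 0) {
    stop("rate_multiplier must be positive")
  }
  n_edge <- nrow(tree$edge)
  base <- if (scheme == "unit") rep(1, n_edge) else lengths
  if (length(base) != n_edge) {
    stop("custom lengths must supply one value per edge (", n_edge, ")")
  }
  if (any(base < 0)) stop("branch lengths must be non-negative")
  tree$edge.length <- base * rate_multiplier
  tree
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the set of non-trivial splits induced by the internal edges of the
#' unrooted version of `tree`, encoded as canonical 0/1 strings over a
#' reference taxon ordering (the lexicographically smallest taxon is always on
#' the '0' side, so each split has a unique key).  Splits are invariant under
#' re-rooting.
#'
#' @param tree a `phylo` object with >= 4 leaves.
#' @param taxa reference taxon ordering; defaults to the sorted leaf labels.
#' @return character vector of split keys with attribute `"taxa"`.
#' @export
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  if (length(tree$tip.label) < 4) stop("splits need at least 4 leaves")
  if (!setequal(tree$tip.label, taxa) ||
      length(taxa) != length(tree$tip.label)) {
    stop("mismatched leaf sets")
  }
  ord <- match(tree$tip.label, taxa)
  keys <- unique(split_strings_cpp(tree$edge, length(taxa),
                                   as.integer(ord - 1L)))
  structure(keys, taxa = taxa)
}

#' Taxa on the clade side of each split
#'
#' The "clade" side of a canonical split is the side *not* containing the
#' lexicographically smallest taxon.
#'
#' @param splits result of [tree_splits()].
#' @return list of character vectors.
#' @export
split_members <- function(splits) {
  taxa <- attr(splits, "taxa")
  lapply(strsplit(unclass(splits), ""), function(bits) taxa[bits == "1"])
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that validate
#' the input and give a parse error with a position for unbalanced
#' parentheses.  `write_newick(read_newick(x))` is the identity on
#' canonicalized trees.
#'
#' @param text a Newick string (or vector of strings, one tree each).
#' @param file optionally read from / write to a file instead.
#' @return `read_newick`: a `phylo` (or `multiPhylo` when several trees);
#'   `write_newick`: character vector of Newick strings (invisibly when
#'   writing to a file).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- readLines(file)
  text <- text[nzchar(trimws(text))]
  for (one in text) {
    depth <- 0
    chars <- strsplit(one, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") depth <- depth - 1
      if (depth < 0) stop("unbalanced ')' at position ", i)
    }
    if (depth != 0) {
      stop("unbalanced '(': ", depth, " unclosed at end of string")
    }
    if (!grepl(";\\s*$", one)) stop("Newick string must end with ';'")
  }
  trees <- ape::read.tree(text = text)
  if (is.null(trees)) stop("could not parse Newick string")
  trees
}

#' @rdname read_newick
#' @param tree a `phylo` or `multiPhylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  out <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
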