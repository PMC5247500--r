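#' Majority-rule consensus tree
#'
#' Contains exactly the non-trivial splits whose frequency across the input
#' trees is strictly greater than `threshold`; for `threshold >= 0.5` those
#' splits are pairwise compatible, and taxa with no qualifying split collapse
#' into polytomies.  No greedy compatibility extension is applied.
#'
#' @param trees a `multiPhylo` (or list of `phylo` / a `posterior_sample`)
#'   on a common leaf set.
#' @param threshold split-frequency cutoff (strict majority by default).
#' @return a `phylo`, possibly polytomous, without branch lengths.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "posterior_sample")) {
    taxa <- sort(trees$taxa)
    keysets <- posterior_split_keys(trees)
  } else {
    if (inherits(trees, "phylo")) trees <- list(trees)
    taxa <- sort(trees[[1]]$tip.label)
    for (tr in trees) {
      if (!setequal(tr$tip.label, taxa) ||
          length(tr$tip.label) != length(taxa)) {
        stop("mismatched leaf sets")
      }
    }
    keysets <- lapply(trees, function(tr) tree_splits(tr, taxa))
  }
  n <- length(keysets)
  tab <- table(unlist(keysets))
  keep <- names(tab)[as.numeric(tab) / n > threshold]
  build_tree_from_splits(keep, taxa)
}

# assemble a (possibly polytomous) phylo from pairwise-compatible canonical
# split keys; clades are oriented away from the first reference taxon, so the
# family of '1'-sides is laminar and nests directly
build_tree_from_splits <- function(keys, taxa) {
  clades <- lapply(strsplit(keys, ""), function(b) which(b == "1"))
  clades <- clades[order(lengths(clades), decreasing = TRUE)]
  build <- function(members, available) {
    inside <- available[vapply(available, function(cl) all(cl %in% members),
                               TRUE)]
    parts <- character(0)
    used <- integer(0)
    while (length(inside)) {
      top <- inside[[1]]           # largest remaining clade is maximal
      rest <- inside[-1]
      sub <- rest[vapply(rest, function(cl) all(cl %in% top), TRUE)]
      parts <- c(parts, build(top, sub))
      used <- c(used, top)
      inside <- rest[!vapply(rest, function(cl) all(cl %in% top), TRUE)]
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(parts, taxa[singles]), collapse = ","), ")")
  }
  txt <- paste0(build(seq_along(taxa), clades), ";")
  ape::read.tree(text = txt)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the non-trivial split sets of two
#' trees on the same leaf set; 0 for identical topologies and at most
#' `2(n-3)` for two fully resolved n-leaf trees.
#'
#' @param tree_a,tree_b `phylo` objects on the same >= 4 leaves.
#' @return integer distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  taxa <- sort(tree_a$tip.label)
  if (!setequal(tree_b$tip.label, taxa) ||
      length(tree_b$tip.label) != length(taxa)) {
    stop("mismatched leaf sets")
  }
  a <- tree_splits(tree_a, taxa)
  b <- tree_splits(tree_b, taxa)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Phylogenetic resolution
#'
#' Fraction of the `n - 3` possible non-trivial splits present in the tree:
#' 1 for a fully resolved (binary) tree, 0 for a star tree.
#'
#' @param tree a `phylo`.
#' @param n_leaves leaf count (defaults to the tree's).
#' @return value in `[0, 1]`.
#' @export
resolution <- function(tree, n_leaves = length(tree$tip.label)) {
  if (n_leaves < 4) stop("resolution undefined for fewer than 4 leaves")
  length(tree_splits(tree)) / (n_leaves - 3)
}

#' Per-node recovery frequencies
#'
#' For each internal node of the rooted generating tree that induces a
#' non-trivial bipartition, the percentage of replicate consensus trees
#' containing that bipartition (rooting of the estimates is never assumed).
#' Node depth is measured in edges from the root.
#'
#' @param generating_tree rooted `phylo` that generated the data.
#' @param consensus_trees list of consensus `phylo`s, one per replicate.
#' @return data.frame of class `node_accuracy` with columns `node`, `depth`,
#'   `clade_size`, `clade` (semicolon-joined labels) and `frequency`
#'   (percent).
#' @export
per_node_accuracy <- function(generating_tree, consensus_trees) {
  if (inherits(consensus_trees, "phylo")) {
    consensus_trees <- list(consensus_trees)
  }
  taxa <- sort(generating_tree$tip.label)
  n_tip <- length(taxa)
  key_sets <- lapply(consensus_trees, function(tr) {
    if (!setequal(tr$tip.label, taxa)) stop("mismatched leaf sets")
    tree_splits(tr, taxa)
  })
  tr <- ape::reorder.phylo(generating_tree, "cladewise")
  root <- n_tip + 1
  depth <- rep(NA_integer_, n_tip + tr$Nnode)
  depth[root] <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  }
  rows <- list()
  for (v in setdiff(seq_len(tr$Nnode) + n_tip, root)) {
    tips <- ape::extract.clade(tr, v)$tip.label
    if (length(tips) < 2 || length(tips) > n_tip - 2) next
    bits <- rep("0", n_tip)
    bits[match(tips, taxa)] <- "1"
    if (bits[1] == "1") bits <- ifelse(bits == "1", "0", "1")
    key <- paste(bits, collapse = "")
    freq <- mean(vapply(key_sets, function(k) key %in% k, TRUE)) * 100
    rows[[length(rows) + 1]] <- data.frame(
      node = v, depth = depth[v], clade_size = length(tips),
      clade = paste(sort(tips), collapse = ";"), frequency = freq)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("node_accuracy", "data.frame")
  out
}

#' Depth-accuracy rank correlation
#'
#' Spearman's rank correlation between per-node recovery frequency and node
#' depth (edges from the root), with average ranks for ties and a two-sided
#' p-value.  A positive correlation means nodes closer to the tips are
#' recovered more often.
#'
#' @param table a [per_node_accuracy()] result (>= 3 nodes).
#' @return list with `rho`, `p_value` and `defined` (FALSE when the accuracy
#'   vector is constant, in which case `rho` is `NA`).
#' @export
depth_accuracy_correlation <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 nodes")
  if (length(unique(table$frequency)) == 1 ||
      length(unique(table$depth)) == 1) {
    return(list(rho = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(
    cor.test(table$frequency, table$depth, method = "spearman",
             alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}
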