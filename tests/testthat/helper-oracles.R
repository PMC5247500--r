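# Independent oracles used across the suite.  All of them enumerate or
# integrate directly and never touch the package's own engines.

# minimum changes of one character on a tree, by exhaustive enumeration of
# internal-node state assignments
brute_fitch <- function(states, tree, k = max(states) + 1L) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  assign <- integer(nnode)
  assign[seq_len(ntip)] <- states[tree$tip.label]
  grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(internal)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign[internal] <- as.integer(grid[g, ])
    changes <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Mk+Gamma likelihood of one character by brute-force summation over
# internal-node assignments, using the closed-form transition matrix
brute_mk_loglik <- function(states, tree, alpha, k, ncat = 4) {
  tree <- ape::reorder.phylo(tree, "postorder")
  rates <- morphobench::gamma_categories(alpha, ncat)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  grid <- do.call(expand.grid, rep(list(1:k), length(internal)))
  tot <- 0
  for (r in rates) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      morphobench::mk_transition(tree$edge.length[e], k, r)
    })
    assign <- integer(nnode)
    assign[seq_len(ntip)] <- states[tree$tip.label] + 1L
    like <- 0
    for (g in seq_len(nrow(grid))) {
      assign[internal] <- as.integer(grid[g, ])
      p <- 1 / k
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * Ps[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
      }
      like <- like + p
    }
    tot <- tot + like / ncat
  }
  log(tot)
}

# naive Robinson-Foulds via character-set comparison of clades
naive_rf <- function(a, b) {
  clades <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- length(tr$tip.label)
    out <- character(0)
    for (v in (ntip + 1):(ntip + tr$Nnode)) {
      tips <- sort(ape::extract.clade(tr, v)$tip.label)
      if (length(tips) >= 2 && length(tips) <= ntip - 2) {
        if (tr$tip.label[order(tr$tip.label)][1] %in% tips) {
          tips <- sort(setdiff(tr$tip.label, tips))
        }
        out <- c(out, paste(tips, collapse = "|"))
      }
    }
    unique(out)
  }
  ca <- clades(a)
  cb <- clades(b)
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

# random morphological matrix over given taxa (uniform states, no model)
random_matrix <- function(n_taxa, n_char, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- matrix(sample(0:(k - 1), n_taxa * n_char, replace = TRUE),
               n_taxa, n_char,
               dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  morpho_matrix(st, ifelse(apply(st, 2, max) <= 1, "binary", "multistate"))
}
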