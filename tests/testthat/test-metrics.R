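test_that("majority-rule consensus follows the strict-majority rule", {
  t1 <- read_newick("((A,B),(C,D),E);")
  t2 <- read_newick("((A,B),(C,E),D);")
  t3 <- read_newick("((A,B),(C,D),E);")
  cons <- majority_rule_consensus(list(t1, t2, t3))
  keys <- tree_splits(cons, sort(t1$tip.label))
  expect_true("01100" %in% keys ||
                any(sapply(split_members(keys),
                           function(s) setequal(s, c("C", "D")))))
  # AB appears 3/3, CD 2/3 -> both kept; CE 1/3 dropped
  expect_length(keys, 2)
  # a split in exactly half of an even sample is dropped
  cons2 <- majority_rule_consensus(list(t1, t2))
  keys2 <- split_members(tree_splits(cons2, sort(t1$tip.label)))
  expect_length(keys2, 1)                        # only AB|CDE survives
  expect_setequal(keys2[[1]], c("C", "D", "E"))  # clade side away from A
})

test_that("consensus of identical trees is that topology", {
  set.seed(9)
  tr <- ape::rtree(10)
  cons <- majority_rule_consensus(list(tr, tr, tr))
  expect_equal(rf_distance(cons, tr), 0)
})

test_that("consensus of the three quartet resolutions is the star tree", {
  trees <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                  read_newick)
  cons <- majority_rule_consensus(trees)
  expect_length(tree_splits(cons), 0)
  expect_equal(resolution(cons, 4), 0)
})

test_that("consensus agrees with ape::consensus on random samples", {
  set.seed(123)
  for (rep in 1:5) {
    trees <- lapply(1:7, function(i) ape::rtree(8,
                                                tip.label = paste0("t", 1:8)))
    mine <- majority_rule_consensus(trees)
    apes <- ape::consensus(trees, p = 0.5)
    expect_equal(rf_distance(mine, apes), 0, info = paste("rep", rep))
  }
})

test_that("consensus rejects mismatched leaf sets", {
  expect_error(majority_rule_consensus(list(read_newick("((A,B),(C,D));"),
                                            read_newick("((A,B),(C,E));"))),
               "mismatched")
})

test_that("RF distance counts the split symmetric difference", {
  a <- read_newick("((A,B),(C,D));")
  b <- read_newick("((A,C),(B,D));")
  expect_equal(rf_distance(a, a), 0)
  expect_equal(rf_distance(a, b), 2)
  star <- ape::stree(8, "star")
  set.seed(4)
  full <- ape::rtree(8, tip.label = star$tip.label)
  expect_equal(rf_distance(full, star), 5)       # n - 3
  expect_error(rf_distance(a, read_newick("((A,B),(C,E));")), "mismatched")
})

test_that("RF agrees with phangorn and satisfies metric axioms", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (rep in 1:10) {
    t1 <- ape::rtree(8, tip.label = paste0("t", 1:8))
    t2 <- ape::rtree(8, tip.label = paste0("t", 1:8))
    t3 <- ape::rtree(8, tip.label = paste0("t", 1:8))
    d12 <- rf_distance(t1, t2)
    expect_equal(d12, as.integer(phangorn::RF.dist(t1, t2)))
    expect_equal(d12, rf_distance(t2, t1))
    expect_lte(d12, rf_distance(t1, t3) + rf_distance(t3, t2))
    expect_equal(d12, naive_rf(t1, t2))
  }
})

test_that("resolution is the non-trivial split fraction", {
  set.seed(14)
  expect_equal(resolution(ape::rtree(32)), 1.0)
  expect_equal(resolution(ape::stree(32, "star")), 0.0)
  trees <- lapply(1:4, function(i) ape::rtree(32,
                                              tip.label = paste0("t", 1:32)))
  cons <- majority_rule_consensus(trees)
  expect_equal(resolution(cons, 32), length(tree_splits(cons)) / 29)
  expect_error(resolution(read_newick("(A,B,C);")), "fewer than 4")
})

test_that("per-node accuracy reproduces hand counts", {
  gen <- read_newick("(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  perfect <- gen
  star <- ape::stree(8, "star")
  star$tip.label <- paste0("t", 1:8)
  # two perfect trees, one star, one partial match
  partial <- read_newick("(((t1,t2),(t3,t4)),(t5,t6,t7,t8));")
  tab <- per_node_accuracy(gen, list(perfect, perfect, star, partial))
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 100))
  get <- function(members) {
    hit <- sapply(strsplit(tab$clade, ";"), setequal, y = members)
    tab$frequency[hit]
  }
  expect_equal(get(c("t1", "t2")), 75)           # in all but the star
  expect_equal(get(c("t5", "t6")), 50)           # lost in star and polytomy
  expect_equal(get(c("t5", "t6", "t7", "t8")), 75)
  # all perfect / all star
  expect_true(all(per_node_accuracy(gen, list(perfect, perfect))$frequency
                  == 100))
  expect_true(all(per_node_accuracy(gen, list(star))$frequency == 0))
})

test_that("node depth is measured in edges from the root", {
  gen <- make_asymmetric_tree(8)
  tab <- per_node_accuracy(gen, list(gen))
  # pectinate: clade sizes 2..6 at depths 6..2 (nontrivial splits only)
  expect_equal(sort(tab$depth), sort(seq(2, 6)))
  expect_equal(tab$depth[tab$clade_size == 2], 6)
})

test_that("depth-accuracy correlation matches cor.test and flags ties", {
  tab <- data.frame(node = 1:10, depth = 1:10,
                    clade = as.character(1:10), clade_size = 2,
                    frequency = c(95, 90, 85, 80, 70, 65, 60, 50, 40, 20))
  res <- depth_accuracy_correlation(tab)
  expect_equal(res$rho, -1)
  tab$frequency <- rev(tab$frequency)
  expect_equal(depth_accuracy_correlation(tab)$rho, 1)
  # with ties: against a direct rank-formula computation
  tab$frequency <- c(90, 90, 80, 80, 80, 60, 50, 50, 30, 10)
  res <- depth_accuracy_correlation(tab)
  r1 <- rank(tab$frequency)
  r2 <- rank(tab$depth)
  rho_direct <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(res$rho, rho_direct, tolerance = 1e-12)
  expect_true(res$defined)
  # constant accuracy: undefined
  tab$frequency <- rep(50, 10)
  expect_false(depth_accuracy_correlation(tab)$defined)
})
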