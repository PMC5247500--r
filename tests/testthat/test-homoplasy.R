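test_that("fitch steps match simple hand-computable cases", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(fitch_steps(c(A = 0, B = 0, C = 1, D = 1), tr), 1L)
  expect_equal(fitch_steps(c(A = 0, B = 1, C = 0, D = 1), tr), 2L)
  expect_equal(fitch_steps(c(A = 1, B = 1, C = 1, D = 1), tr), 0L)
  expect_error(fitch_steps(c(A = 0, B = 0, C = 1), tr), "missing")
})

test_that("fitch equals exhaustive internal-assignment enumeration", {
  set.seed(202)
  for (n in c(4, 5, 6)) {
    for (rep in 1:6) {
      tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
      k <- sample(2:4, 1)
      states <- setNames(sample(0:(k - 1), n, replace = TRUE),
                         paste0("t", 1:n))
      expect_equal(fitch_steps(states, tr),
                   brute_fitch(states, tr, k),
                   info = sprintf("n=%d k=%d rep=%d", n, k, rep))
    }
  }
})

test_that("fitch agrees with phangorn on larger random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(303)
  tr <- ape::rtree(20, tip.label = paste0("t", 1:20))
  m <- random_matrix(20, 50, k = 4)
  pd <- phangorn::phyDat(m$states, type = "USER", levels = 0:3)
  ph <- phangorn::fitch(tr, pd, site = "site")[attr(pd, "index")]
  expect_equal(fitch_steps(m, tr), ph, ignore_attr = TRUE)
})

test_that("consistency index follows its definition", {
  tr <- read_newick("((A,B),(C,D));")
  # one character at its minimum: CI = 1
  m1 <- morpho_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                             dimnames = list(c("A", "B", "C", "D"), NULL)),
                      "binary")
  expect_equal(consistency_index(m1, tr), 1.0)
  # convergent character: m = 1, s = 2 -> CI = 0.5
  m2 <- morpho_matrix(matrix(c(0L, 1L, 0L, 1L), 4, 1,
                             dimnames = list(c("A", "B", "C", "D"), NULL)),
                      "binary")
  expect_equal(fitch_steps(m2, tr), 2L)   # brute-checked above
  expect_equal(consistency_index(m2, tr), 0.5)
  # all-invariant matrix: undefined
  m3 <- morpho_matrix(matrix(0L, 4, 3,
                             dimnames = list(c("A", "B", "C", "D"), NULL)),
                      rep("binary", 3))
  expect_error(consistency_index(m3, tr), "undefined")
})

test_that("CI is invariant to column order and state relabelling", {
  set.seed(44)
  tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
  m <- random_matrix(8, 30, k = 3)
  ci0 <- consistency_index(m, tr)
  perm <- sample(30)
  m_perm <- morpho_matrix(m$states[, perm], m$char_type[perm])
  expect_equal(consistency_index(m_perm, tr), ci0)
  relab <- m$states
  relab[] <- c(2L, 0L, 1L)[relab + 1L]          # permute state labels
  m_rel <- morpho_matrix(relab, rep("multistate", 30))
  expect_equal(consistency_index(m_rel, tr), ci0)
})

test_that("homoplasy target covers [0.26, 1] and normalizes", {
  tg <- homoplasy_target()
  expect_equal(tg$bin_edges[1], 0.26)
  expect_equal(tg$bin_edges[length(tg$bin_edges)], 1.0)
  expect_equal(sum(tg$proportions), 1)
  expect_true(all(tg$proportions > 0))
  expect_error(homoplasy_target(bin_edges = c(0.3, 0.5, 1.0)))
})

test_that("bin quotas apportion exactly by largest remainder", {
  tg <- homoplasy_target(bin_edges = c(0.26, 0.5, 0.75, 1.0),
                         proportions = c(0.5, 0.3, 0.2))
  expect_equal(morphobench:::bin_quotas(tg, 10), c(5L, 3L, 2L))
  expect_equal(sum(morphobench:::bin_quotas(tg, 7)), 7L)
})

test_that("rejection sampler fills quotas exactly and respects CI bounds", {
  tr <- make_asymmetric_tree(16)
  gen <- matrix_generator(tr, 60)
  tg <- homoplasy_target()
  log_file <- tempfile(fileext = ".csv")
  s <- bin_match_sampler(gen, tg, n_total = 20, seed = 5,
                         log_file = log_file)
  expect_length(s$matrices, 20)
  expect_true(all(s$ci >= 0.26 & s$ci <= 1))
  hist <- tabulate(s$bin, nbins = length(tg$proportions))
  expect_equal(hist, morphobench:::bin_quotas(tg, 20))
  lg <- read.csv(log_file)
  expect_equal(sum(lg$accepted), 20)
  expect_equal(nrow(lg), s$n_attempts)
  unlink(log_file)
  # determinism
  s2 <- bin_match_sampler(gen, tg, n_total = 20, seed = 5)
  expect_identical(s$ci, s2$ci)
  expect_identical(s$matrices[[7]]$states, s2$matrices[[7]]$states)
})

test_that("degenerate one-bin target confines all accepted CIs", {
  tr <- make_asymmetric_tree(16)
  gen <- matrix_generator(tr, 60)
  props <- rep(0, 15)
  props[8] <- 1                                  # CI in [0.61, 0.66)
  tg <- homoplasy_target(proportions = props)
  s <- bin_match_sampler(gen, tg, n_total = 5, seed = 6)
  expect_true(all(s$ci >= 0.61 & s$ci < 0.66))
})

test_that("unfillable quotas raise an informative error", {
  gen_stub <- function(seed) list(matrix = NULL, ci = 0.99)
  props <- rep(0, 15)
  props[1] <- 1
  tg <- homoplasy_target(proportions = props)
  expect_error(
    bin_match_sampler(gen_stub, tg, n_total = 2, seed = 1,
                      max_attempts = 50),
    "unfilled quotas")
})
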