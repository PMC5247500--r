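test_that("replicate parameters are exponential draws with fixed kappa/pi", {
  p <- draw_replicate_params(1)
  expect_identical(p, draw_replicate_params(1))
  expect_equal(p$kappa, 2)
  expect_equal(p$pi, c(0.2, 0.2, 0.3, 0.3))
  set.seed(123)
  draws <- replicate(10000, {
    p <- draw_replicate_params()
    c(p$alpha, p$mu)
  })
  # exponential mean 1: sample means within 3 standard errors
  se <- 1 / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[1, ]) - 1), 3 * se)
  expect_lt(abs(mean(draws[2, ]) - 1), 3 * se)
})

test_that("sim_params validates its fields", {
  expect_error(sim_params(pi = c(0.5, 0.5, 0, 0)))
  expect_error(sim_params(kappa = -1))
  expect_error(sim_params(binary_fraction = 1.5))
})

test_that("HKY transition matrix has the required limits", {
  p <- sim_params()
  expect_equal(hky_transition_matrix(0, 1, p), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  P <- hky_transition_matrix(0.5, 1, p)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  Pinf <- hky_transition_matrix(500, 1, p)
  for (i in 1:4) expect_equal(unname(Pinf[i, ]), p$pi, tolerance = 1e-8)
  expect_error(hky_transition_matrix(-1, 1, p), "non-negative")
})

test_that("HKY transition matrix matches the matrix-exponential oracle", {
  p <- sim_params()
  dec <- morphobench:::hky_decomposition(p)
  for (t in c(0.1, 0.5, 2)) {
    expect_equal(unname(hky_transition_matrix(t, 1, p)),
                 ape::matexpo(dec$Q * t), tolerance = 1e-10)
  }
  # detailed balance of the normalized generator: pi_i q_ij = pi_j q_ji
  Q <- dec$Q
  expect_equal(p$pi * Q[, 2], p$pi[2] * Q[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(p$pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("long-branch simulation reproduces the stationary distribution", {
  p <- sim_params(alpha = 100)
  star <- assign_branch_lengths(ape::stree(8, "star"), rate_multiplier = 50)
  nuc <- simulate_nucleotides(star, p, 10000, seed = 99)
  freq <- as.numeric(table(factor(nuc, levels = 1:4))) / length(nuc)
  se <- sqrt(p$pi * (1 - p$pi) / length(nuc))
  expect_true(all(abs(freq - p$pi) < 3 * se + 1e-3))
})

test_that("per-character gamma rates concentrate as alpha grows", {
  p_hi <- sim_params(alpha = 100)
  p_lo <- sim_params(alpha = 0.1)
  tr <- make_symmetric_tree(4)
  v_hi <- var(attr(simulate_nucleotides(tr, p_hi, 10000, seed = 1), "rates"))
  v_lo <- var(attr(simulate_nucleotides(tr, p_lo, 10000, seed = 1), "rates"))
  expect_lt(v_hi, v_lo)
  expect_lt(v_hi, 0.05)   # Var = 1/alpha
})

test_that("recoding produces the configured binary:multistate ratio", {
  tr <- make_symmetric_tree(8)
  nuc <- simulate_nucleotides(tr, sim_params(), 100, seed = 5)
  m <- recode_characters(nuc, 0.55, seed = 6)
  expect_equal(sum(m$char_type == "binary"), 55)
  expect_equal(sum(m$char_type == "multistate"), 45)
  m2 <- recode_characters(simulate_nucleotides(tr, sim_params(), 1000,
                                               seed = 7), 0.55, seed = 8)
  expect_equal(sum(m2$char_type == "binary"), 550)
  # ties round up
  nuc9 <- simulate_nucleotides(tr, sim_params(), 10, seed = 9)
  expect_equal(sum(recode_characters(nuc9, 0.55, seed = 1)$char_type ==
                     "binary"), 6)
})

test_that("binary columns are exactly the R/Y image of their nucleotides", {
  tr <- make_asymmetric_tree(16)
  m <- simulate_matrix(tr, sim_params(alpha = 2, mu = 0.3), seed = 21)
  nuc <- attr(m, "nucleotides")
  ry <- c(0L, 1L, 0L, 1L)
  for (j in which(m$char_type == "binary")) {
    expect_identical(m$states[, j], setNames(ry[nuc[, j]], rownames(nuc)),
                     ignore_attr = TRUE)
  }
  for (j in which(m$char_type == "multistate")) {
    expect_identical(m$states[, j], nuc[, j] - 1L, ignore_attr = TRUE)
  }
})

test_that("binary state frequencies approach one half", {
  # pi_A + pi_G = pi_C + pi_T = 0.5, so R/Y coding is symmetric
  p <- sim_params(alpha = 100)
  star <- assign_branch_lengths(ape::stree(8, "star"), rate_multiplier = 50)
  m <- recode_characters(simulate_nucleotides(star, p, 5000, seed = 31), 1)
  f0 <- mean(m$states == 0L)
  expect_lt(abs(f0 - 0.5), 0.01)
})

test_that("simulation is bit-identical given (tree, params, seed)", {
  tr <- make_asymmetric_tree(8)
  p <- sim_params(alpha = 1.2, mu = 0.4)
  m1 <- simulate_matrix(tr, p, seed = 77)
  m2 <- simulate_matrix(tr, p, seed = 77)
  expect_identical(m1$states, m2$states)
  expect_identical(m1$char_type, m2$char_type)
})

test_that("matrix writers and readers round-trip", {
  tr <- make_symmetric_tree(8)
  m <- simulate_matrix(tr, sim_params(n_characters = 20), seed = 3)
  nex <- tempfile(fileext = ".nex")
  phy <- tempfile(fileext = ".phy")
  tnt <- tempfile(fileext = ".tnt")
  write_nexus(m, nex)
  write_phylip(m, phy)
  write_tnt(m, tnt)
  back_nex <- read_nexus_matrix(nex)
  back_phy <- read_phylip_matrix(phy)
  expect_identical(unname(back_nex$states[m$taxa, ]), unname(m$states))
  expect_identical(unname(back_phy$states[m$taxa, ]), unname(m$states))
  expect_true(any(grepl("xread", readLines(tnt))))
  unlink(c(nex, phy, tnt))
})
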