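quartet_matrix <- function(n_ab = 12, n_noise = 8, seed = 1) {
  set.seed(seed)
  st <- cbind(matrix(c(0L, 0L, 1L, 1L), 4, n_ab),
              matrix(sample(0:1, 4 * n_noise, replace = TRUE), 4))
  rownames(st) <- c("A", "B", "C", "D")
  morpho_matrix(st, rep("binary", ncol(st)))
}

test_that("prior-only sampling recovers the priors", {
  m <- quartet_matrix()
  post <- run_mcmc(m, mcmc_config(n_generations = 2e5, prior_only = TRUE,
                                  seed = 42))
  # 5 branches, Exp(10) prior each
  expect_equal(mean(post$tree_length) / 5, 0.1, tolerance = 0.02)
  expect_equal(mean(post$alpha), 1, tolerance = 0.1)
  # topology uniform over the three quartet resolutions
  freq <- table(unlist(morphobench:::posterior_split_keys(post))) /
    length(post$edge)
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < 0.1))
})

test_that("strong quartet data puts the generating split above 0.95", {
  set.seed(7)
  st <- cbind(matrix(c(0L, 0L, 1L, 1L), 4, 1000),
              matrix(sample(0:1, 4 * 60, replace = TRUE), 4))
  rownames(st) <- c("A", "B", "C", "D")
  m <- morpho_matrix(st, rep("binary", ncol(st)))
  post <- suppressWarnings(run_mcmc(m, mcmc_config(n_generations = 5e4,
                                                   seed = 9)))
  freq <- table(unlist(morphobench:::posterior_split_keys(post))) /
    length(post$edge)
  expect_gt(freq[["0011"]], 0.95)
})

test_that("split posterior matches a prior-integration oracle on weak data", {
  # moderate 4-taxon data; fixed alpha (single rate category) so the only
  # latent variables are topology and branch lengths
  m <- quartet_matrix(n_ab = 5, n_noise = 10, seed = 3)
  cfg <- mcmc_config(n_generations = 4e5, seed = 13,
                     n_gamma_categories = 1,
                     move_weights = c(nni = 0.45, spr = 0.1,
                                      brlen = 0.45, alpha = 0))
  post <- run_mcmc(m, cfg)
  freq <- table(factor(unlist(morphobench:::posterior_split_keys(post)),
                       levels = c("0011", "0101", "0110"))) /
    length(post$edge)
  # oracle: P(T) proportional to the prior-expectation of the likelihood,
  # estimated by Monte Carlo over iid Exp(10) branch lengths
  quartets <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                     function(x) ape::unroot(read_newick(x)))
  set.seed(99)
  draws <- matrix(rexp(5 * 4000, rate = 10), ncol = 5)
  marg <- sapply(quartets, function(q) {
    mean(apply(draws, 1, function(bl) {
      q$edge.length <- bl
      exp(mk_loglik(m, q, alpha = 1, mk_config(n_gamma_categories = 1)))
    }))
  })
  oracle <- marg / sum(marg)
  expect_true(all(abs(as.numeric(freq) - oracle) < 0.06),
              info = paste("mcmc:", paste(round(freq, 3), collapse = " "),
                           "oracle:", paste(round(oracle, 3), collapse = " ")))
})

test_that("sampling is deterministic and sized by the burn-in arithmetic", {
  m <- quartet_matrix(seed = 5)
  cfg <- mcmc_config(n_generations = 2e4, n_runs = 2, seed = 31)
  p1 <- run_mcmc(m, cfg)
  p2 <- run_mcmc(m, cfg)
  expect_identical(p1$logL, p2$logL)
  expect_identical(p1$edge[[17]], p2$edge[[17]])
  # 2 runs x (200 stored - 25% burn-in)
  expect_length(p1$logL, 2 * 150)
  expect_equal(unique(p1$run), c(1, 2))
})

test_that("metropolis-coupled chains sample the same posterior", {
  m <- quartet_matrix(n_ab = 8, n_noise = 10, seed = 6)
  base <- mcmc_config(n_generations = 1e5, seed = 21)
  mc3 <- mcmc_config(n_generations = 1e5, n_chains = 3, seed = 22)
  f1 <- table(factor(unlist(morphobench:::posterior_split_keys(
    run_mcmc(m, base))), levels = c("0011", "0101", "0110")))
  f2 <- table(factor(unlist(morphobench:::posterior_split_keys(
    run_mcmc(m, mc3))), levels = c("0011", "0101", "0110")))
  expect_true(all(abs(f1 - f2) / 750 < 0.12))
})

test_that("convergence diagnostics separate agreeing and disagreeing runs", {
  m <- quartet_matrix(n_ab = 20, n_noise = 5, seed = 8)
  post <- suppressWarnings(run_mcmc(m, mcmc_config(n_generations = 1e5,
                                                   n_runs = 2, seed = 77)))
  d <- convergence_diagnostics(post)
  expect_lt(d$asdsf, 0.05)
  expect_true(d$pass)
  expect_lt(abs(d$psrf_alpha - 1), 0.2)
  # identical runs: ASDSF exactly zero
  half <- function(p, r) {
    p2 <- p
    keep <- p$run == r
    for (f in c("edge", "blen", "tip_order")) p2[[f]] <- p[[f]][keep]
    for (f in c("alpha", "logL", "log_prior", "tree_length", "generation",
                "run")) p2[[f]] <- p[[f]][keep]
    p2
  }
  r1 <- half(post, 1)
  expect_equal(convergence_diagnostics(r1, r1)$asdsf, 0)
  # tiny noisy runs should flag failure
  noise <- random_matrix(8, 6, k = 2, seed = 123)
  bad <- suppressWarnings(run_mcmc(noise,
                                   mcmc_config(n_generations = 2000,
                                               sample_interval = 10,
                                               n_runs = 2, seed = 5)))
  expect_false(convergence_diagnostics(bad)$pass)
  # mismatched configurations are rejected
  a <- suppressWarnings(run_mcmc(m, mcmc_config(n_generations = 2000,
                                                seed = 1)))
  b <- suppressWarnings(run_mcmc(m, mcmc_config(n_generations = 4000,
                                                seed = 1)))
  expect_error(convergence_diagnostics(a, b), "mismatched")
})
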