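test_that("Mk transition matrix obeys its closed form and limits", {
  expect_equal(mk_transition(0, 2), diag(2), tolerance = 1e-14)
  expect_equal(mk_transition(1e4, 2), matrix(0.5, 2, 2), tolerance = 1e-12)
  tau <- 0.5
  expect_equal(mk_transition(tau, 2)[1, 1], 0.5 + 0.5 * exp(-2 * tau / 1))
  # closed form against the matrix exponential for k = 2..4
  for (k in 2:4) {
    Q <- matrix(1 / (k - 1), k, k)
    diag(Q) <- -1
    for (t in c(0.2, 1, 3)) {
      expect_equal(mk_transition(t, k), ape::matexpo(Q * t),
                   tolerance = 1e-10)
    }
  }
  expect_error(mk_transition(-0.1, 2), "non-negative")
})

test_that("gamma categories have mean one and match quadrature", {
  for (alpha in c(0.1, 0.5, 1, 5)) {
    r <- gamma_categories(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-8)
  }
  expect_equal(gamma_categories(1e4, 4), rep(1, 4), tolerance = 0.02)
  # quadrature oracle: mean of each equal-probability gamma slice
  alpha <- 0.5
  q <- qgamma(c(0, 0.25, 0.5, 0.75, 1), alpha, rate = alpha)
  oracle <- sapply(1:4, function(i) {
    4 * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                  q[i], q[i + 1], rel.tol = 1e-10)$value
  })
  expect_equal(gamma_categories(alpha, 4), oracle, tolerance = 1e-6)
})

test_that("gamma categories match phangorn's discretization", {
  skip_if_not_installed("phangorn")
  for (alpha in c(0.3, 1, 2.5)) {
    expect_equal(gamma_categories(alpha, 4),
                 as.numeric(phangorn::discrete.gamma(alpha, 4)),
                 tolerance = 1e-9)
  }
})

test_that("two-taxon binary likelihood has the textbook closed form", {
  tr <- read_newick("(A:0.3,B:0.4);")
  same <- morpho_matrix(matrix(c(0L, 0L), 2, 1,
                               dimnames = list(c("A", "B"), NULL)), "binary")
  tau <- 0.7
  expect_equal(mk_loglik(same, tr, alpha = 1,
                         mk_config(n_gamma_categories = 1)),
               log(0.5 * (0.5 + 0.5 * exp(-2 * tau))), tolerance = 1e-12)
})

test_that("pruning equals brute-force summation over internal states", {
  set.seed(404)
  for (rep in 1:8) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    k <- sample(2:4, 1)
    sts <- setNames(sample(0:(k - 1), n, replace = TRUE), paste0("t", 1:n))
    sts[1:2] <- c(0L, k - 1L)                    # guarantee all k observed?
    kc <- length(unique(sts))
    m <- morpho_matrix(matrix(sts, n, 1,
                              dimnames = list(paste0("t", 1:n), NULL)),
                       if (max(sts) <= 1) "binary" else "multistate")
    alpha <- runif(1, 0.2, 3)
    expect_equal(mk_loglik(m, tr, alpha),
                 brute_mk_loglik(setNames(match(sts, sort(unique(sts))) - 1L,
                                          names(sts)),
                                 tr, alpha, k = max(2, kc)),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting", {
  set.seed(505)
  tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
  m <- random_matrix(8, 20, k = 3)
  ll0 <- mk_loglik(m, tr, alpha = 0.8)
  r2 <- ape::root(ape::unroot(tr), "t5", resolve.root = TRUE)
  r2$edge.length[r2$edge.length == 0] <- 1e-9
  expect_equal(mk_loglik(m, r2, alpha = 0.8), ll0, tolerance = 1e-6)
})

test_that("Mkv conditioning raises the likelihood of variable characters", {
  set.seed(606)
  tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
  m <- random_matrix(6, 15, k = 2)
  keep <- apply(m$states, 2, function(x) length(unique(x)) > 1)
  m <- morpho_matrix(m$states[, keep, drop = FALSE], m$char_type[keep])
  ll_mk <- mk_loglik(m, tr, alpha = 1, mk_config(ascertainment = "none"))
  ll_mkv <- mk_loglik(m, tr, alpha = 1,
                      mk_config(ascertainment = "variable"))
  expect_gt(ll_mkv, ll_mk)
})

test_that("ML search finds the best of the three quartet topologies", {
  set.seed(707)
  quartets <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                     function(x) ape::unroot(read_newick(x)))
  for (rep in 1:3) {
    st <- matrix(sample(0:1, 4 * 40, replace = TRUE), 4, 40,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
    st[, 1:25] <- c(0L, 0L, 1L, 1L)              # signal towards AB|CD
    st[, 26:30] <- c(0L, 1L, 1L, 0L)             # some conflict
    m <- morpho_matrix(st, rep("binary", 40))
    fit <- ml_search(m, mk_config(), seed = rep)
    # oracle: optimize each labelled topology separately (multi-start)
    oracle <- sapply(quartets, function(q) {
      best <- -Inf
      for (s0 in c(0.05, 0.2, 1)) {
        opt <- optim(c(rep(log(s0), nrow(q$edge)), 0), function(p) {
          q$edge.length <- exp(p[-length(p)])
          -mk_loglik(m, q, alpha = exp(p[length(p)]))
        }, method = "L-BFGS-B", lower = log(1e-7), upper = log(50))
        best <- max(best, -opt$value)
      }
      best
    })
    expect_equal(sort(tree_splits(fit$tree)),
                 sort(tree_splits(quartets[[which.max(oracle)]])))
    # the returned likelihood must dominate every alternative topology's
    # optimum, so the topology decision is supported by the reported score
    expect_gte(fit$logL, max(oracle[-which.max(oracle)]))
  }
})

test_that("ML recovers a fixed 6-taxon topology from abundant data", {
  gen <- read_newick("(((t1:0.2,t2:0.2):0.2,(t3:0.2,t4:0.2):0.2):0.2,(t5:0.2,t6:0.4):0.2);")
  m <- simulate_matrix(gen, sim_params(alpha = 2, mu = 1,
                                       n_characters = 5000), seed = 11)
  fit <- ml_search(m, mk_config(), seed = 2)
  expect_equal(rf_distance(fit$tree, gen), 0)
})
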