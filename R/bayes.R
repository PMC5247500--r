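#' Bayesian MCMC configuration
#'
#' Defaults are the desk-scale preset (100,000 generations, a single cold
#' chain, one run is 1/10 of the full-scale chain length); `preset =
#' "paper"` restores the full-scale settings (1,000,000 generations sampled
#' every 100th by four Metropolis-coupled chains, two independent runs).
#'
#' Priors: i.i.d. Exponential(10) branch lengths, Exponential(1) gamma shape,
#' uniform over unrooted topologies.  Proposal mix (by weight): NNI 0.4,
#' SPR 0.1, branch-length multiplier 0.4, shape multiplier 0.1.
#'
#' @param n_generations chain length.
#' @param sample_interval store every `sample_interval`-th generation; must
#'   divide `n_generations`.
#' @param n_runs independent runs (combined after burn-in).
#' @param n_chains Metropolis-coupled chains per run (1 = plain MCMC).
#' @param burn_in_fraction fraction of stored samples discarded per run.
#' @param heat_delta increment of the MC3 heating temperature.
#' @param swap_interval generations between chain-swap proposals.
#' @param bl_prior_rate,alpha_prior_rate exponential prior rates.
#' @param move_weights proposal weights (nni, spr, brlen, alpha).
#' @param bl_lambda,alpha_lambda multiplier-proposal tuning constants.
#' @param n_gamma_categories discretized gamma categories.
#' @param ascertainment `"none"` (Mk) or `"variable"` (Mkv).
#' @param prior_only force a constant likelihood (prior-recovery runs).
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed; run seeds are derived from it.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 1e5, sample_interval = 100,
                        n_runs = 1, n_chains = 1, burn_in_fraction = 0.25,
                        heat_delta = 0.1, swap_interval = 10,
                        bl_prior_rate = 10, alpha_prior_rate = 1,
                        move_weights = c(nni = 0.4, spr = 0.1,
                                         brlen = 0.4, alpha = 0.1),
                        bl_lambda = 2, alpha_lambda = 1.4,
                        n_gamma_categories = 4,
                        ascertainment = c("none", "variable"),
                        prior_only = FALSE,
                        preset = c("desk", "paper"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_generations <- 1e6
    n_runs <- 2
    n_chains <- 4
  }
  stopifnot(n_generations > 0, burn_in_fraction >= 0, burn_in_fraction < 1,
            n_generations %% sample_interval == 0, length(move_weights) == 4)
  structure(list(n_generations = n_generations,
                 sample_interval = as.integer(sample_interval),
                 n_runs = as.integer(n_runs), n_chains = as.integer(n_chains),
                 burn_in_fraction = burn_in_fraction,
                 heat_delta = heat_delta,
                 swap_interval = as.integer(swap_interval),
                 bl_prior_rate = bl_prior_rate,
                 alpha_prior_rate = alpha_prior_rate,
                 move_weights = move_weights, bl_lambda = bl_lambda,
                 alpha_lambda = alpha_lambda,
                 n_gamma_categories = as.integer(n_gamma_categories),
                 ascertainment = match.arg(ascertainment),
                 prior_only = isTRUE(prior_only), preset = preset,
                 seed = seed),
            class = "mcmc_config")
}

#' Bayesian Mk+Gamma tree inference by MCMC
#'
#' Metropolis-Hastings (optionally Metropolis-coupled) sampling of unrooted
#' topology, branch lengths and gamma shape under the Mk+Gamma likelihood.
#' Runs `config$n_runs` independent chains from independent random starting
#' trees, discards the burn-in fraction of each run's stored samples and
#' combines the rest.
#'
#' @param x a [morpho_matrix] with >= 4 taxa.
#' @param config an [mcmc_config()].
#' @return an object of class `posterior_sample`: lists `edge` / `blen` of
#'   sampled trees (ape-style edge matrices over `taxa`), vectors `alpha`,
#'   `logL`, `log_prior`, `tree_length`, `generation`, `run`, plus
#'   `acceptance` (per-run proposal/acceptance counts) and the `config`.
#' @export
run_mcmc <- function(x, config = mcmc_config()) {
  taxa <- x$taxa
  if (length(taxa) < 4) stop("MCMC needs at least 4 taxa")
  mkcfg <- mk_config(n_gamma_categories = config$n_gamma_categories,
                     ascertainment = config$ascertainment)
  sd <- mk_state_data(x, mkcfg)
  out <- list()
  acc <- list()
  for (r in seq_len(config$n_runs)) {
    run_seed <- (config$seed * 1009 + r * 9973) %% 2147483629
    set.seed(run_seed)
    start <- ape::unroot(ape::rtree(length(taxa), tip.label = taxa))
    start$edge.length <- rep(0.1, nrow(start$edge))
    ord <- match(start$tip.label, taxa)
    st <- sd$states[ord, , drop = FALSE]
    res <- mcmc_cpp(start$edge, start$edge.length, length(taxa), st,
                    sd$kchar, config$n_gamma_categories,
                    as.integer(config$n_generations), config$sample_interval,
                    1.0, config$bl_prior_rate, config$alpha_prior_rate,
                    as.numeric(config$move_weights), config$bl_lambda,
                    config$alpha_lambda, config$prior_only,
                    config$ascertainment == "variable", config$n_chains,
                    config$heat_delta, config$swap_interval,
                    as.double(run_seed))
    n_samp <- length(res$alpha)
    keep <- seq_len(n_samp) > floor(config$burn_in_fraction * n_samp)
    if (sum(res$accepted[1:2]) == 0 && !config$prior_only) {
      warning("no topology move was accepted in run ", r,
              "; the chain is not mixing over tree space")
    }
    acc[[r]] <- list(proposed = res$proposed, accepted = res$accepted)
    out[[r]] <- list(edge = res$edge[keep], blen = res$blen[keep],
                     alpha = res$alpha[keep], logL = res$logL[keep],
                     log_prior = res$log_prior[keep],
                     tree_length = res$tree_length[keep],
                     generation = res$generation[keep],
                     run = rep(r, sum(keep)), taxa_order = ord)
  }
  combined <- list(
    taxa = taxa,
    # tip i of every sampled tree is taxon taxa[taxa_order][i] of that run
    edge = do.call(c, lapply(out, `[[`, "edge")),
    blen = do.call(c, lapply(out, `[[`, "blen")),
    tip_order = do.call(c, lapply(out, function(o) {
      rep(list(o$taxa_order), length(o$edge))
    })),
    alpha = do.call(c, lapply(out, `[[`, "alpha")),
    logL = do.call(c, lapply(out, `[[`, "logL")),
    log_prior = do.call(c, lapply(out, `[[`, "log_prior")),
    tree_length = do.call(c, lapply(out, `[[`, "tree_length")),
    generation = do.call(c, lapply(out, `[[`, "generation")),
    run = do.call(c, lapply(out, `[[`, "run")),
    acceptance = acc, config = config)
  class(combined) <- "posterior_sample"
  combined
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf(
    "posterior_sample: %d trees (%d run%s), %d taxa; mean logL %.2f\n",
    length(x$edge), max(x$run), if (max(x$run) > 1) "s" else "",
    length(x$taxa), mean(x$logL)))
  invisible(x)
}

#' Sampled trees as phylo objects
#'
#' @param sample a `posterior_sample`.
#' @param which indices of the stored samples (default all).
#' @return a `multiPhylo`.
#' @export
posterior_trees <- function(sample, which = seq_along(sample$edge)) {
  trees <- lapply(which, function(i) {
    edge_to_phylo(sample$edge[[i]], sample$taxa[sample$tip_order[[i]]],
                  sample$blen[[i]])
  })
  class(trees) <- "multiPhylo"
  trees
}

# split keys of every sampled tree (list of character vectors)
posterior_split_keys <- function(sample) {
  taxa_ref <- sort(sample$taxa)
  lapply(seq_along(sample$edge), function(i) {
    labels <- sample$taxa[sample$tip_order[[i]]]
    ord <- match(labels, taxa_ref)
    split_strings_cpp(sample$edge[[i]], length(taxa_ref),
                      as.integer(ord - 1L))
  })
}

#' Between-run convergence diagnostics
#'
#' Average standard deviation of split frequencies (ASDSF) between two runs,
#' and potential scale reduction factors (PSRF) for the gamma shape and the
#' tree length; mirrors the usual MrBayes-style checks.
#'
#' @param sample_run1,sample_run2 `posterior_sample`s from identically
#'   configured runs (or one combined sample with `run` labels 1 and 2 and
#'   `sample_run2` omitted).
#' @param min_freq splits below this frequency in both runs are ignored for
#'   the ASDSF.
#' @param asdsf_threshold pass/fail threshold (default 0.05).
#' @return list with `asdsf`, `psrf_alpha`, `psrf_tree_length` and `pass`.
#' @export
convergence_diagnostics <- function(sample_run1, sample_run2 = NULL,
                                    min_freq = 0.1,
                                    asdsf_threshold = 0.05) {
  if (is.null(sample_run2)) {
    runs <- sort(unique(sample_run1$run))
    if (length(runs) < 2) stop("need two runs for diagnostics")
    splits_by_run <- split(posterior_split_keys(sample_run1),
                           sample_run1$run)
    alpha_by_run <- split(sample_run1$alpha, sample_run1$run)
    tl_by_run <- split(sample_run1$tree_length, sample_run1$run)
  } else {
    c1 <- sample_run1$config
    c2 <- sample_run2$config
    if (!identical(c1[setdiff(names(c1), "seed")],
                   c2[setdiff(names(c2), "seed")])) {
      stop("runs have mismatched configurations")
    }
    splits_by_run <- list(posterior_split_keys(sample_run1),
                          posterior_split_keys(sample_run2))
    alpha_by_run <- list(sample_run1$alpha, sample_run2$alpha)
    tl_by_run <- list(sample_run1$tree_length, sample_run2$tree_length)
  }
  freq_of <- function(keys_list) {
    tab <- table(unlist(keys_list)) / length(keys_list)
    setNames(as.numeric(tab), names(tab))
  }
  freqs <- lapply(splits_by_run, freq_of)
  all_keys <- unique(unlist(lapply(freqs, names)))
  fm <- sapply(freqs, function(f) {
    ifelse(all_keys %in% names(f), f[all_keys], 0)
  })
  if (!is.matrix(fm)) fm <- matrix(fm, nrow = length(all_keys))
  keep <- apply(fm, 1, max) >= min_freq
  asdsf <- if (any(keep)) {
    mean(apply(fm[keep, , drop = FALSE], 1, function(f) sqrt(var(f))))
  } else 0
  psrf <- function(chains) {
    m <- length(chains)
    n <- min(lengths(chains))
    chains <- lapply(chains, function(x) x[seq_len(n)])
    means <- vapply(chains, mean, 0)
    vars <- vapply(chains, var, 0)
    B <- n * var(means)
    W <- mean(vars)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  res <- list(asdsf = asdsf, psrf_alpha = psrf(alpha_by_run),
              psrf_tree_length = psrf(tl_by_run),
              pass = asdsf < asdsf_threshold)
  res
}
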