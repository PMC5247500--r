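#' Factorial study design
#'
#' The full experiment crosses two 32-taxon generating-tree shapes with three
#' matrix sizes; each cell receives `replicates` homoplasy-calibrated
#' matrices analysed by every method.  The full-scale preset `"paper"` (1000
#' replicates per cell, 6000 matrices in total, full-length MCMC) matches
#' the original study design; the desk preset keeps every scientific setting but
#' runs 50 replicates per cell and the short-chain MCMC so a study finishes
#' on one workstation.
#'
#' @param shapes subset of `c("symmetric", "asymmetric")`.
#' @param sizes character counts per matrix.
#' @param replicates matrices per (shape, size) cell.
#' @param methods subset of `c("ew", "iw", "ml", "bayes")`.
#' @param n_taxa leaves of the generating trees.
#' @param master_seed master RNG seed; every replicate is reproducible from
#'   `(master_seed, cell, replicate)`.
#' @param preset `"desk"` or `"paper"`; presets fill `replicates` and the
#'   MCMC settings unless these are given explicitly.
#' @param target a [homoplasy_target()].
#' @param parsimony,mk,mcmc per-method configurations.
#' @return an object of class `study_design`.
#' @export
study_design <- function(shapes = c("symmetric", "asymmetric"),
                         sizes = c(100, 350, 1000),
                         replicates = NULL,
                         methods = c("ew", "iw", "ml", "bayes"),
                         n_taxa = 32, master_seed = 1,
                         preset = c("desk", "paper"),
                         target = homoplasy_target(),
                         parsimony = parsimony_config(),
                         mk = mk_config(),
                         mcmc = NULL) {
  preset <- match.arg(preset)
  shapes <- match.arg(shapes, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(replicates)) replicates <- if (preset == "paper") 1000 else 50
  if (is.null(mcmc)) mcmc <- mcmc_config(preset = preset)
  structure(list(shapes = shapes, sizes = sizes,
                 replicates = as.integer(replicates), methods = methods,
                 n_taxa = as.integer(n_taxa), master_seed = master_seed,
                 preset = preset, target = target, parsimony = parsimony,
                 mk = mk, mcmc = mcmc),
            class = "study_design")
}

#' Number of matrices a design will simulate
#'
#' Dry-run count: shapes x sizes x replicates, without generating anything.
#'
#' @param design a [study_design()].
#' @return integer count.
#' @export
count_design_matrices <- function(design) {
  length(design$shapes) * length(design$sizes) * design$replicates
}

generating_tree <- function(shape, n_taxa) {
  switch(shape,
         symmetric = make_symmetric_tree(n_taxa),
         asymmetric = make_asymmetric_tree(n_taxa),
         stop("unknown tree shape: ", shape))
}

# deterministic sub-seed for (cell, replicate, purpose); stays below 2^31
derive_seed <- function(master, shape, size, replicate = 0, purpose = "") {
  key <- paste(shape, size, replicate, purpose, sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1048573
  (master * 1223 + h * 2011 + 17) %% 2147483629
}

# run one inference method on one matrix; returns the replicate's tree
# sample and its consensus
infer_one <- function(method, m, design, seed) {
  if (method %in% c("ew", "iw")) {
    cfg <- design$parsimony
    cfg$weighting <- if (method == "ew") "equal" else "implied"
    cfg$seed <- seed
    res <- parsimony_search(m, cfg)
    cons <- majority_rule_consensus(res$best_trees)
    list(consensus = cons, score = res$best_score,
         sample_size = length(res$best_trees))
  } else if (method == "ml") {
    res <- ml_search(m, design$mk, seed = seed)
    list(consensus = res$tree, score = res$logL, sample_size = 1L)
  } else if (method == "bayes") {
    cfg <- design$mcmc
    cfg$seed <- seed
    post <- run_mcmc(m, cfg)
    cons <- majority_rule_consensus(post)
    list(consensus = cons, score = mean(post$logL),
         sample_size = length(post$edge))
  } else {
    stop("unknown method: ", method)
  }
}

#' Run one cell of the study
#'
#' Simulates `replicates` homoplasy-calibrated matrices on the requested
#' generating tree, runs every method on each, reduces each method's tree
#' sample to its majority-rule consensus, and scores accuracy (RF distance to
#' the generating tree), resolution, per-node recovery and the
#' depth-accuracy correlation.
#'
#' @param shape `"symmetric"` or `"asymmetric"`.
#' @param n_characters matrix width.
#' @param design a [study_design()].
#' @param replicates overrides the design's replicate count.
#' @return list with `results` (one row per replicate x method: `rf`,
#'   `resolution`, `ci`, `score`), `node_accuracy` (per method),
#'   `spearman` (per method), and the per-replicate `consensus` trees.
#' @export
run_cell <- function(shape, n_characters, design = study_design(),
                     replicates = design$replicates) {
  tree <- generating_tree(shape, design$n_taxa)
  gen <- matrix_generator(tree, n_characters)
  cell_seed <- derive_seed(design$master_seed, shape, n_characters,
                           purpose = "sim")
  sampled <- bin_match_sampler(gen, design$target, replicates,
                               seed = cell_seed)
  rows <- list()
  consensus <- list()
  for (meth in design$methods) consensus[[meth]] <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    m <- sampled$matrices[[i]]
    for (meth in design$methods) {
      seed_i <- derive_seed(design$master_seed, shape, n_characters, i, meth)
      fit <- infer_one(meth, m, design, seed_i)
      consensus[[meth]][[i]] <- fit$consensus
      rows[[length(rows) + 1]] <- data.frame(
        shape = shape, n_characters = n_characters, replicate = i,
        method = meth, ci = sampled$ci[i],
        rf = rf_distance(fit$consensus, tree),
        resolution = resolution(fit$consensus, design$n_taxa),
        score = fit$score, sample_size = fit$sample_size)
    }
  }
  node_acc <- lapply(consensus, function(cl) per_node_accuracy(tree, cl))
  spearman <- lapply(node_acc, depth_accuracy_correlation)
  list(results = do.call(rbind, rows), node_accuracy = node_acc,
       spearman = spearman, consensus = consensus, ci = sampled$ci,
       n_attempts = sampled$n_attempts)
}

#' Run the full factorial study
#'
#' @param design a [study_design()].
#' @param verbose print progress per cell.
#' @return object of class `study_results`: `results` (all replicate rows),
#'   `table1` (mean and range of RF per cell x method), `table2` (Spearman
#'   depth-accuracy tests per cell x method), `node_accuracy` (per cell).
#' @export
run_study <- function(design = study_design(), verbose = interactive()) {
  all_rows <- list()
  node_acc <- list()
  spear <- list()
  for (shape in design$shapes) {
    for (size in design$sizes) {
      if (verbose) {
        message(sprintf("cell %s / %d characters ...", shape, size))
      }
      cell <- run_cell(shape, size, design)
      key <- paste(shape, size, sep = "_")
      all_rows[[key]] <- cell$results
      node_acc[[key]] <- cell$node_accuracy
      spear[[key]] <- cell$spearman
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  out <- list(results = results,
              table1 = summarise_rf(results),
              table2 = summarise_spearman(spear),
              node_accuracy = node_acc,
              design = design)
  class(out) <- "study_results"
  out
}

# Table-1 analogue: mean and range of RF per cell x method
summarise_rf <- function(results) {
  agg <- aggregate(rf ~ shape + n_characters + method, data = results,
                   FUN = function(x) c(mean = mean(x), min = min(x),
                                       max = max(x)))
  data.frame(agg[c("shape", "n_characters", "method")],
             mean_rf = agg$rf[, "mean"], min_rf = agg$rf[, "min"],
             max_rf = agg$rf[, "max"])
}

# Table-2 analogue: Spearman depth-accuracy test per cell x method
summarise_spearman <- function(spear) {
  rows <- list()
  for (key in names(spear)) {
    parts <- strsplit(key, "_")[[1]]
    for (meth in names(spear[[key]])) {
      s <- spear[[key]][[meth]]
      rows[[length(rows) + 1]] <- data.frame(
        shape = parts[1], n_characters = as.numeric(parts[2]),
        method = meth, rho = s$rho, p_value = s$p_value,
        defined = s$defined)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_results <- function(x, ...) {
  cat("study_results:", nrow(x$results), "replicate x method rows\n")
  cat("\nMean (min-max) Robinson-Foulds distance:\n")
  print(x$table1, row.names = FALSE)
  invisible(x)
}

#' Write result tables and figures
#'
#' Writes the Table-1/Table-2 analogues and the per-replicate rows as CSV,
#' an RF-against-resolution density figure per method, and per-node accuracy
#' against depth figures.
#'
#' @param results a `study_results`.
#' @param output_dir directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
make_report <- function(results, output_dir) {
  if (!nrow(results$results)) stop("empty results")
  if (!length(unique(results$results$method))) stop("no methods in results")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    replicates = file.path(output_dir, "replicates.csv"),
    table1 = file.path(output_dir, "rf_summary.csv"),
    table2 = file.path(output_dir, "depth_accuracy.csv"),
    fig1 = file.path(output_dir, "rf_vs_resolution.pdf"),
    fig2 = file.path(output_dir, "node_accuracy.pdf"))
  write.csv(results$results, paths["replicates"], row.names = FALSE)
  write.csv(results$table1, paths["table1"], row.names = FALSE)
  write.csv(results$table2, paths["table2"], row.names = FALSE)

  df <- results$results
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = rf, y = resolution)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_grid(shape ~ method + n_characters) +
    ggplot2::labs(x = "Robinson-Foulds distance", y = "resolution") +
    ggplot2::theme_bw()
  enough <- nrow(df) >= 50 && var(df$rf) > 0 && var(df$resolution) > 0
  if (enough) {
    p1 <- p1 + ggplot2::geom_density_2d(colour = "firebrick", na.rm = TRUE)
  }
  suppressWarnings(ggplot2::ggsave(paths["fig1"], p1, width = 11,
                                   height = 6))

  acc_rows <- list()
  for (key in names(results$node_accuracy)) {
    for (meth in names(results$node_accuracy[[key]])) {
      tab <- results$node_accuracy[[key]][[meth]]
      tab$cell <- key
      tab$method <- meth
      acc_rows[[paste(key, meth)]] <- tab
    }
  }
  acc <- do.call(rbind, acc_rows)
  p2 <- ggplot2::ggplot(acc, ggplot2::aes(x = depth, y = frequency,
                                          colour = method)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", se = FALSE, formula = y ~ x) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "node depth (edges from root)",
                  y = "recovery frequency (%)") +
    ggplot2::theme_bw()
  suppressWarnings(ggplot2::ggsave(paths["fig2"], p2, width = 9, height = 6))
  invisible(paths)
}
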