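# morphobench

Simulation-based benchmarking of phylogenetic inference from discrete
morphological (phenotype) characters.

Morphology is the only evidence for placing most extinct taxa on the tree
of life, but the field is split over how to analyse discrete character
matrices: equal-weights parsimony (EW), implied-weights parsimony (IW,
Goloboff fit with concavity *k* = 2), maximum-likelihood estimation under
Lewis's Mk model, or Bayesian estimation under the same model.  Since the
true tree is unknowable for real data, methods can only be ranked on
simulations from known trees.  `morphobench` implements such a study
end-to-end, with its own native engines for all four methods:

1. **Simulate** characters on fixed 32-taxon generating trees at the two
   extremes of tree shape (fully balanced and fully pectinate, both
   ultrametric) under HKY+Γ(continuous) with κ = 2,
   π = (0.2, 0.2, 0.3, 0.3), and per-replicate shape and rate drawn i.i.d.
   from Exponential(mean 1); recode 55% of columns to binary (purine /
   pyrimidine) and the rest to 4-state integers.
2. **Calibrate homoplasy** by rejection sampling: each matrix is admitted
   only if its consistency index CI = Σmᵢ / Σsᵢ on the generating tree
   falls in an unfilled bin of a target distribution spanning the
   empirical bounds [0.26, 1.0] in 0.05 bins.
3. **Infer** trees with EW and IW parsimony (random-addition +
   NNI/SPR hill climbing, all tied optima retained), maximum-likelihood
   Mk+Γ (pruning likelihood, NNI + quasi-Newton branch lengths), and
   Bayesian Mk+Γ (Metropolis–Hastings over topology, branch lengths and
   gamma shape; optional Metropolis coupling; Mkv ascertainment correction
   available for empirical matrices).
4. **Score** every method's majority-rule consensus against the generating
   tree: Robinson–Foulds distance, resolution, per-node recovery
   frequency, and the Spearman correlation between node accuracy and depth
   from the root.

Trees are `ape::phylo` objects throughout; matrices read/write NEXUS
(`DATATYPE=STANDARD`), relaxed PHYLIP and TNT `xread`.  The compute-heavy
engines (Fitch counting, Mk+Γ pruning with cached partials, parsimony
search, MCMC) are implemented in C++ via Rcpp.

## Worked example

```r
library(morphobench)

tree <- make_asymmetric_tree(32)            # pectinate, ultrametric
sampled <- bin_match_sampler(matrix_generator(tree, 100),
                             homoplasy_target(), n_total = 5, seed = 42)
m <- sampled$matrices[[1]]
m
#> morpho_matrix: 32 taxa x 100 characters (55 binary, 45 multistate)
sampled$ci[1]
#> [1] 0.604    # consistency index on the generating tree

ew <- parsimony_search(m, parsimony_config(seed = 1))
ew$best_score; length(ew$best_trees)
#> [1] 132      # total Fitch steps of the optimal trees
#> [1] 500      # distinct topologies tying that score (capped)
cons <- majority_rule_consensus(ew$best_trees)
rf_distance(cons, tree); resolution(cons, 32)
#> [1] 35       # Robinson-Foulds distance to the truth (max possible 58)
#> [1] 0.55     # over half of the possible splits asserted

post <- run_mcmc(m, mcmc_config(seed = 1))  # desk preset: 100k generations
cons_b <- majority_rule_consensus(post)
rf_distance(cons_b, tree); resolution(cons_b, 32)
#> [1] 28       # closer to the truth ...
#> [1] 0.03     # ... by asserting almost nothing it is not sure of
```

One hard 100-character matrix, and the study's central contrast in
miniature: the parsimony consensus asserts far more structure and pays for
it in accuracy, while the Bayesian consensus is barely resolved but closer
to the generating topology.

The full factorial experiment (shapes × sizes × replicates × methods) runs
through `run_study(study_design(preset = "desk"))`, and `make_report()`
writes the summary tables (mean and range of RF per cell and method,
depth–accuracy correlations) and figures.  A thin command-line wrapper
with `simulate` / `infer` / `evaluate` / `run-study` subcommands is in
`inst/scripts/morphobench-cli.R`.

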