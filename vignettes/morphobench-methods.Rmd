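---
title: "Benchmarking phylogenetic inference on simulated morphology: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking phylogenetic inference on simulated morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphobench)
```

## The question the package addresses

Discrete morphological characters are the only evidence available for
placing most fossil taxa, yet the field disagrees about how to analyse
them: equal-weights parsimony (EW), implied-weights parsimony (IW),
maximum-likelihood estimation under the Mk model, or Bayesian estimation
under the same model.  Because the true tree is never known for empirical
data, the only way to rank these methods is simulation from known
generating trees.  `morphobench` implements such a simulation study
end-to-end: it simulates binary/multistate character matrices whose level
of homoplasy is calibrated to an empirical profile, infers trees with all
four methods using its own desk-scale engines, and scores every estimate
against the generating topology.

## Generating trees

Two 32-taxon rooted trees at the extremes of tree shape are used: a fully
balanced (symmetric) tree and a fully pectinate (asymmetric, "caterpillar")
tree.  Leaves are labelled `t1..t32` deterministically so that the same
clade means the same thing in every replicate.

Both trees are **ultrametric** with root-to-tip height 1 expected
substitution per character (before the per-replicate rate is applied), with
splits evenly spaced in time.  This is a deliberate design choice, and it
matters.  If instead every edge is given equal length, the pectinate tree
is no harder to recover than the balanced one — each internal edge then
carries just as much expected change — and none of the depth-dependent
behaviour that motivates the comparison appears.  Under ultrametry the
pectinate tree's deep internodes are short relative to the long pendant
branches of early-diverging leaves, so deep clades carry little signal and
much noise: accuracy falls from tip to root, and the asymmetric tree is
substantially harder at every matrix size.  The overall height is
statistically innocuous because the replicate rate multiplies the whole
tree and the homoplasy filter (below) conditions on the realized amount of
change.

## The character simulation model

Characters are first simulated as nucleotides under HKY with continuous
gamma rate variation and then recoded to morphology-like states:

* transition/transversion ratio $\kappa = 2$;
* stationary frequencies $\pi = (0.2, 0.2, 0.3, 0.3)$ in A, C, G, T order
  (the uneven $\pi$ keeps the generating model from collapsing into the Mk
  model, which would bias the study toward the Mk-based methods; the
  assignment of the printed values to bases is a convention — R/Y recoding
  makes binary characters insensitive to within-purine or within-pyrimidine
  swaps);
* per-replicate gamma shape $\alpha$ and substitution rate $\mu$ drawn
  i.i.d. from Exponential distributions with mean 1;
* per-character rate $r \sim \Gamma(\alpha, \alpha)$ (continuous, mean 1);
  the discretized gamma appears only at inference;
* 55% of columns are recoded purine/pyrimidine (A,G → 0; C,T → 1), the
  remainder map A,C,G,T → 0,1,2,3; which columns become binary is
  re-randomized each replicate (the counts, `round(0.55 N)`, are exact).

The HKY generator is normalized to one expected substitution per unit
branch length at stationarity, so branch lengths are in the conventional
units.  Simulation uses the spectral decomposition of the (reversible)
generator, symmetrized through $\pi^{1/2}$ for numerical stability, and is
validated in the tests against `ape::matexpo` and against stationarity on
long-branch star trees.

## Homoplasy calibration

Raw $(\alpha, \mu)$ draws produce many matrices that are either nearly
saturated or nearly invariant.  To keep the simulated matrices comparable
to real cladistic data, every candidate matrix is scored by its consistency
index (CI) on the generating tree,

$$\mathrm{CI} = \frac{\sum_i m_i}{\sum_i s_i},$$

with $s_i$ the Fitch step count of character $i$ and $m_i$ its minimum
conceivable changes (observed states − 1); invariant characters contribute
to neither sum.  Matrices are then admitted by rejection sampling against a
binned target distribution of CI spanning the empirical bounds
$[0.26, 1.0]$ in steps of 0.05.  Because $(1.0 - 0.26)/0.05$ is not an
integer, the final bin is $[0.96, 1.0]$ (closed, width 0.04); all other
bins are half-open $[\ell, \ell + 0.05)$.  Per-bin quotas are apportioned
by largest remainder, so the accepted histogram equals the quota vector
exactly and every accepted CI lies within the empirical bounds.

The default per-bin proportions are a **documented stand-in**: a triangular
density peaking near CI = 0.6, clipped below at 2% per bin.  The empirical
distribution this emulates (survey data of published morphological
matrices) is not shipped with the package; users with a specific empirical
profile should pass their own `proportions` to `homoplasy_target()`.  The
CI used for admission is computed on the *generating* tree — cheap,
deterministic, and available before any search — rather than on a
most-parsimonious tree, which would require a full search per candidate.

One consequence of conditioning only on CI is worth knowing: a matrix can
land in a high-CI bin either because it evolved slowly and cleanly or
because a tiny $\alpha$ left almost no variable characters.  The second
kind yields a poorly resolved consensus whatever the method, and produces
occasional large Robinson–Foulds outliers even at 1000 characters.

## Inference engines

All four engines are native implementations (C++ behind R wrappers); no
external phylogenetics program is invoked.

**Parsimony (EW and IW).**  Fitch counting is exact for binary trees and
for the trifurcating-root representation of unrooted trees.  EW minimizes
total steps; IW maximizes the Goloboff fit $\sum_i k/(k + e_i)$ with extra
steps $e_i = s_i - m_i$ and concavity $k = 2$.  The search uses random
addition-sequence starting trees followed by steepest-ascent NNI sweeps,
optionally with random SPR improvement attempts.  All distinct topologies
tying the best score across starts are retained (capped at 500), and the
tied set is broadened by random equal-score NNI walks across the optimal
plateau, since the method's "tree sample" for consensus purposes is the
set of optimal trees and hill climbing alone visits few of its members.  On
exhaustive enumerations at six and seven taxa the search attains the global
optimum in every tested instance with the default ten starts.

**Maximum likelihood (Mk+Γ).**  Felsenstein pruning with per-character
state count $k_c$ = number of observed states (floored at 2; a fixed
2/4-by-type rule is available), uniform root frequencies $1/k_c$, and four
equal-probability discretized gamma categories.  The search alternates
L-BFGS-B optimization of log branch lengths and log $\alpha$ (multi-start,
to guard against the multimodal length surface of small noisy matrices)
with steepest-ascent NNI rounds in which each neighbour's central edge is
re-optimized before comparison.  ML output is a single fully resolved tree,
which is also its own "consensus" — resolution is 1 by construction.

**Bayesian (Mk+Γ).**  Metropolis–Hastings over unrooted topology, branch
lengths and gamma shape.  Priors are i.i.d. Exponential(10) on branch
lengths, Exponential(1) on $\alpha$, uniform on topologies; none are stated
by the study this design follows, so the usual defaults of Bayesian
phylogenetics software are adopted and exposed in `mcmc_config()`.
Proposals: NNI 40%, SPR 10%, branch-length multiplier 40%, shape multiplier
10%.  The SPR move prunes a uniformly chosen valid subtree and regrafts at
a uniform position along a uniformly chosen valid target edge; the number
of valid choices is invariant under the move, so the only Hastings term is
the ratio of the split and merged edge lengths.  Conditional likelihoods
are cached per node and only the path to the root is recomputed after a
move; a rejected move simply re-marks the same path so the next evaluation
restores it from the reverted state.  The cached evaluation agrees exactly
with a fresh full pruning pass at every sampled state (asserted in tests),
and the sampler reproduces its priors under a constant likelihood and an
exhaustive 4-taxon posterior oracle within Monte Carlo error.  Ascertainment
correction (Mkv, conditioning each character on being variable) is
available for empirical matrices but off for simulated data, which contain
their invariant characters.

Metropolis coupling (heated chains with state swaps) is implemented and
configurable but off in the desk preset; correctness targets the cold
chain's stationary distribution, and at these data sizes a single chain
mixes well (between-run ASDSF ≈ 0.02–0.04 at 100,000 generations).

## Scoring

All methods are reduced to a majority-rule consensus (splits with frequency
strictly above 0.5; no greedy extension), compared to the generating tree
by the Robinson–Foulds distance (symmetric difference of non-trivial split
sets; maximum $2(n-3) = 58$ at 32 taxa), and summarized by resolution
(fraction of the $n - 3$ possible splits present).  Per-node accuracy is
the percentage of replicate consensus trees containing the node's
(unrooted) bipartition; node depth is counted in edges from the root, a
natural unit here because splits are evenly spaced in time.  Clades whose
bipartition is trivial (the root's, and a root child's when its sibling is
a leaf) are excluded.  Depth–accuracy association uses Spearman's rank
correlation with average ranks and a two-sided p-value (`stats::cor.test`);
a positive $\rho$ means tipward nodes are recovered more often.

## Study scales and runtime choices

The full published design is 2 shapes × 3 sizes × 1000 replicates = 6000
matrices with 1,000,000-generation Metropolis-coupled MCMC, two runs per
matrix — cluster-scale work.  The package therefore ships two presets:

* `paper`: the full design (kept for fidelity; `count_design_matrices()`
  dry-runs it);
* `desk` (default): 50 replicates per cell and 100,000-generation
  single-chain MCMC with 25% burn-in, which reproduces the qualitative
  structure of the results on one workstation.

The bundled tests scale further down where a quantity is expensive but its
signal is large: the Table-1-style reproductions use 100 replicates for
equal-weights parsimony at 1000 characters and 30 replicates for the
Bayesian cells at 100 characters; the monotonicity-with-size checks use
6–12 replicates per cell and 50,000-generation chains for the larger
Bayesian cells.  These sizes are stated here so that the Monte Carlo error
implied by each check is explicit.

## Numerical details and edge cases

* Discretized gamma uses equal-probability slices with conditional-mean
  rates, renormalized to mean exactly 1 (matches `phangorn::discrete.gamma`
  to 10 digits).
* The Mk transition matrix uses the closed form
  $P_{\text{same}}(\tau) = 1/k + (k-1)/k \, e^{-k\tau/(k-1)}$; pruning
  rescales partials per node only when they fall below $10^{-120}$, and the
  gamma mixture is combined by log-sum-exp.
* Parsimony fit ties are resolved at $10^{-9}$; IW fits of partial trees
  during stepwise addition clamp $e_i \ge 0$ (on full trees the clamp is
  inert).
* Majority-rule consensus construction orients every split away from the
  lexicographically smallest taxon, so the retained clades form a laminar
  family and nest directly into a tree.
* All randomness flows from explicit integer seeds: replicate seeds are
  derived deterministically from a master seed, R-side draws use R's RNG,
  and the C++ engines use an own splitmix64 stream seeded from R, so
  results are bit-reproducible across platforms.

## What passing tests do and do not show

The simulator emulates the generating conditions of the study it follows:
fixed 32-taxon trees at two shape extremes, HKY+Γ characters recoded
55:45 binary:multistate, and CI-calibrated homoplasy.  It does not emulate
missing data, polymorphic or ordered characters, correlated characters,
ascertainment bias in character selection, or taxon sampling effects — all
common in real matrices.  Agreement with the published mean accuracies
therefore supports the engines and the study logic, not a claim that any
method will behave identically on a particular empirical dataset.  Two
stand-ins are documented above (the CI target density and the generating
branch lengths); both are configurable, and the shipped defaults were
chosen once on scientific grounds rather than fitted to the published
numbers.

## Known limitations

* The parsimony search is a desk-scale surrogate (NNI/SPR hill climbing
  with random restarts), not a TNT-grade heuristic; equivalence is
  demonstrated only as score-optimality on small instances.
* ML ignores topology uncertainty entirely (as in the study design: no
  bootstrap), which is partly why it scores worst — its single fully
  resolved tree pays the full Robinson–Foulds price for every wrong split.
* The Bayesian engine implements Mk+Γ(+v) only; no partitioning, no rate
  multipliers per character type.
* CI-based admission conditions on the generating tree, not on a
  most-parsimonious tree; `ci_tree = "mp"` was considered and rejected
  because it would require a tree search per candidate matrix inside the
  rejection loop.
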