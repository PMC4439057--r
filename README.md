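# cladistinct

Tools for the analysis layer of Bayesian total-evidence phylogenetics of
clade-structured groups such as gall wasps (Cynipidae): summarizing
posterior tree samples from multiple independent MCMC runs,
reconstructing ancestral states of discrete morphological and
life-history characters under the Mk model, and scoring how
*distinctive* and how *unique* each clade's reconstructed ancestral
traits are.

## What it does

**Posterior tree-sample summaries.** Given MrBayes-style `.t` tree
samples (translate tables resolved) and `.p` scalar traces from several
independent runs, the package applies burn-in (default: the initial 25%
of samples), computes per-clade posterior probabilities as the mean
split frequency across runs with the across-run standard deviation as
Monte-Carlo error (flagged when ≥ 0.01), builds majority-rule consensus
trees showing only splits above a display threshold (default 70%), and
evaluates the standard convergence diagnostics: the average standard
deviation of split frequencies (ASDSF, convergence rule < 0.05) and the
Gelman–Rubin potential scale reduction factor (PSRF, rule < 1.01),

    PSRF = sqrt( ((n-1)/n * W + B/n) / W ),

with `W` the mean within-run variance and `B` the between-run variance
of a scalar parameter. Monophyly hypotheses — a required clade plus
"floating" taxa free to sit inside or outside — are assessed by their
frequency in the pooled sample, with "< 1/(N+1)" reporting when no
sampled tree satisfies the constraint.

**Mk ancestral states.** For multistate ordered and unordered characters
with `{..}` polymorphism and `?` missing data, the package computes
Felsenstein-pruning likelihoods and marginal ancestral-state posterior
distributions under the Mk model (uniform state frequencies; ordered
characters change only between adjacent states) with discrete-gamma
rate variation across characters, and averages the per-node state
probabilities over a posterior tree sample: the PP of a trait at a
clade's ancestor is the mean of the per-tree marginal probabilities at
that clade's subtending node.

**Distinctness and uniqueness indices.** For a focal clade and a trait
(a particular state of a character),

    D = PP(clade) - mean over comparison nodes of PP
    U = PP(clade) - max  over comparison nodes of PP

where the comparison set is the other clades plus the group's common
ancestor. Both indices have a maximum of 1.0; distinctness is high for
unusual traits, uniqueness only for traits found nowhere else. Ranked
top-6 tables at two decimals reproduce the usual diagnostic-trait
report layout.

**GC-composition diagnostics.** Per-taxon and per-group GC fractions by
partition and codon position (gaps and ambiguity codes excluded), the
bookkeeping behind compositional-bias comparisons between, e.g.,
outgroups and focal clades at third codon positions.

**Synthetic data.** Seeded generators produce every input the pipeline
reads: clade-structured Yule trees (named tribes monophyletic by
construction, with controlled crown/stem depth structure), Mk character
matrices with recorded ancestral states, HKY alignments with
clade-specific GC equilibria, and multi-run pseudo-posterior tree
samples whose split frequencies have analytically known targets.

## Worked example

```r
library(cladistinct)

rec <- simulation_recipe(
  seed = 1008,
  clades = c(TriA = 5, TriB = 4, TriC = 4, TriD = 3, TriE = 3, TriF = 3),
  n_outgroup = 4, tree_depth = 0.3,
  characters = list(counts = c(`2` = 10, `3` = 4), alpha = 1, planted = 1),
  posterior = list(runs = 2, n_per_run = 30, perturb_p = 0.1))

sim  <- pipeline_simulate(list(recipe = rec, out_dir = "fixture"))
summ <- pipeline_summarize(list(
  tree_files = file.path("fixture", c("run1.t", "run2.t")),
  out_dir = "out"))
summ$asdsf
#> [1] 0.005589777

clades <- c(sim$clades, list(ancestor = unlist(sim$clades)))
res <- pipeline_ancestral_indices(list(
  tree_files = file.path("fixture", c("run1.t", "run2.t")),
  matrix_file = file.path("fixture", "characters.nex"),
  clades = clades, ancestor = "ancestor", alpha = 1, out_dir = "out"))
rank_traits(res$indices, "TriA", "distinctness", top_n = 3)
#>   clade character state     value   tie
#> 1  TriA        14     1 0.9749375 FALSE
#> 2  TriA         1     0 0.3652885 FALSE
#> 3  TriA        12     0 0.3282034 FALSE
```

The ASDSF of 0.006 says the two pseudo-posterior runs sample the same
split distribution (well under the 0.05 convergence rule). The planted
clade-diagnostic character (index 14, state 1 — fixed in TriA and
absent elsewhere) ranks first for TriA with distinctness 0.97: its
ancestral PP in TriA is near 1 while the mean over the other five
tribes and the group ancestor is near 0. `out/report_distinctness.tsv`
holds the full six-trait-per-clade table at two decimals.

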