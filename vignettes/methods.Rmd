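---
title: "Models and methods behind cladistinct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cladistinct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cladistinct implements the analysis layer that sits downstream of a
Bayesian total-evidence phylogenetic inference: it consumes posterior
tree samples and discrete character matrices, and produces clade
supports with Monte-Carlo error, convergence diagnostics, marginal
ancestral-state reconstructions under the Mk model, and the
distinctness/uniqueness indices that diagnose clades by their
reconstructed ancestral traits. This vignette records the models, the
defaults and why they are set where they are, the numerical choices,
and what the synthetic-data generators do and do not emulate. Tree
inference itself (Metropolis-coupled MCMC, substitution-model
averaging) is out of scope: posterior samples are inputs, read from
MrBayes-style files or simulated.

## Posterior summaries and convergence

A `tree_sample` holds one ordered list of trees per independent run.
Burn-in removes the first `ceiling(fraction * n)` samples of each run;
the default fraction is 0.25, the customary "discard the initial 25%"
rule. The ceiling rule is a deliberate choice for fractional counts (10
samples at 0.25 drop 3, not 2), so short test runs behave predictably.

Clade support is bookkept on unrooted bipartitions. Each split is
canonicalized as the side not containing the alphabetically first
taxon, which makes split keys invariant under rerooting (a tested
invariant). The reported posterior probability of a clade is the
arithmetic mean of its per-run frequencies; the across-run sample
standard deviation (n−1 denominator) is the Monte-Carlo error, flagged
in reports when it reaches the 0.01 display rule. Means of per-run
frequencies equal pooled frequencies when runs are equal length, which
is how the hypothesis-frequency estimator and the support table are
cross-checked in the tests.

ASDSF averages, over every split reaching a minimum frequency (default
0.10, the usual MrBayes-style inclusion rule; configurable) in at least
one run, the across-run standard deviation of its frequencies.
Identical runs give exactly 0; independent same-distribution runs of
1,000 trees land well under the 0.05 convergence rule. PSRF is the
classic Gelman–Rubin statistic, `sqrt(((n-1)/n * W + B/n)/W)`, applied
per scalar parameter without rank-normalization — matching the
reporting of MrBayes-era analyses; `coda::gelman.diag` is used as an
independent oracle in the test suite, never as the implementation.

The majority-rule consensus includes exactly the splits whose raw
frequency is *strictly greater* than the threshold (default 0.70, the
usual "only clades above 70% shown" display rule); ties at the
threshold are excluded, and node labels carry the exact frequencies
with no smoothing. Splits above 0.5 are pairwise compatible, so the
consensus is assembled by nesting clades from largest to smallest.

Monophyly hypotheses are expressed as a required taxon set plus a
floating set whose members may sit inside or outside the clade. A tree
satisfies the constraint iff the smallest clade containing the required
taxa contains nothing outside required ∪ floating — equivalent to the
existence of a floating subset completing a monophyletic group, which
is how the test suite checks it (by subset enumeration). The posterior
probability of a hypothesis is estimated as its frequency in the pooled
post-burn-in sample with a binomial standard error; when no tree
qualifies, the report states an upper bound below `1/(N+1)` rather
than a hard zero. Studies often obtain such probabilities from
constrained runs instead; the frequency estimator targets the same
quantity and is the form that can be validated at desk scale, which is
why it is the one implemented.

## The Mk model and marginal ancestral states

Discrete characters evolve under the Mk model: k states, uniform
stationary frequencies, all changes equally likely (unordered) or
restricted to adjacent states (ordered). Generators are normalized to
one expected change per unit branch length at stationarity, so branch
lengths read in expected changes per character. Rate variation across
characters uses the mean-of-class discrete gamma with equal-probability
classes (default 4 categories, the common default; shape `alpha` has no
variation at `Inf`). Category rates are renormalized to mean exactly 1.

Likelihoods use Felsenstein pruning with per-node rescaling of partial
likelihoods (log factors carried separately), so 100-leaf trees stay in
range — verified against small-tree consistency and against a
brute-force enumeration oracle (sums over all internal-node state
assignments with independently computed transition matrices) at
tolerance 1e-10. Polymorphic and missing cells enter as tip partial
vectors with 1 for every allowed state; a taxon absent from a column is
treated as fully missing. Two codings are available: plain Mk
(`conditioning = "none"`, the default) and variable-only
(`conditioning = "variable"`), which divides by the probability of a
variable pattern; the choice is recorded in outputs because published
matrices rarely state which coding their software assumed.

Marginal ancestral distributions combine the downward (subtree) and
upward (rest-of-tree) partials at a node, summed over gamma categories
weighted by each category's likelihood contribution, and normalized
over states. Transition matrices come from the eigendecomposition of
the (symmetric) Mk generator. Over a posterior sample, the PP of a
state at a clade's ancestor is the arithmetic mean of the per-tree
marginals at the clade's subtending node; trees in which the clade is
not monophyletic are skipped for that clade and counted, because
constraint-enforced samples contain every clade in every tree while
unconstrained samples need the skip-and-log path. "Ancestor" means the
crown MRCA throughout; modal-state ties break toward the lowest state
index and are flagged.

## The distinctness and uniqueness indices

For a focal clade and a trait (one state of one character),
distinctness subtracts from the clade's ancestral PP the mean PP of the
same trait over the comparison nodes, and uniqueness subtracts the
maximum. The comparison set defaults to all other clades in the table
plus the node named as the group ancestor, each with equal weight — so
with 12 focal clades the mean divisor is 12 (11 other clades plus the
ancestor). Equal weighting of the ancestor is an interpretation choice:
the definition speaks of the trait "among the other clades and in the
ancestor" without stating weights, and a single equal-weight node is
the plain reading. Since a mean never exceeds a maximum, U ≤ D always;
both indices live in [−1, 1] and attain 1.0 exactly when the focal PP
is 1 and every comparison PP is 0 — the signature of a clean
synapomorphy. Traits with zero PP everywhere are retained at index 0 so
trait inventories stay complete. Reports print two decimals; machine
output keeps full precision.

## File formats

The NEXUS character-matrix reader is implemented in the package because
standard sequence readers do not handle `{..}` polymorphism for
morphological matrices or `ctype` ordering statements. It accepts
interleaved and non-interleaved DATA/CHARACTERS blocks, `symbols`
lists (default `0123456789`), `charset` partitions and
`ctype ordered:` declarations; the ordering map is supplied by the file
or by the caller, never hard-coded. Gaps are treated as missing (full
ambiguity) by default — morphological gap codings rarely carry state
information — with an option to refuse gap-bearing files instead.
Per-character state-space sizes are written to a private NEXUS block on
output because states above the highest observed one cannot be
recovered from the data alone; readers fall back to
max-observed-state + 1 when the block is absent. Character and state
numbers are reported 0-based ("character 1 state 0" style). Tree
samples are Newick lists or NEXUS TREES blocks with translate tables
(via ape), with sampling generations recovered from tree names; scalar
traces are tab-separated with an optional bracketed ID line. Trees
without branch lengths are usable for topology-level summaries only
and are assigned unit lengths with a warning.

## GC composition

GC fractions count only unambiguous A/C/G/T; gaps and ambiguity codes
— including S, which denotes G-or-C — are excluded from numerator and
denominator alike, a conservative rule recorded in the output. Codon
position slices are computed from a per-partition reading-frame offset;
incomplete trailing codons contribute their columns to whichever
positions they reach, so the three position classes always partition
the partition. Group summaries (mean, min, quartiles, max per named
taxon group) depend only on membership, not input order. No numeric
targets exist for published compositional-bias figures, so validation
is structural: simulated clades with shifted GC equilibria must
separate in the group summaries.

## Synthetic data: what it emulates, and what it does not

The default recipe mirrors the shape of a total-evidence gall-wasp
dataset: 103 taxa in 12 ingroup tribes (sizes 20, 12, 10, 9, 8, 8, 7,
6, 5, 4, 3, 3) plus 8 outgroups, 239 discrete characters (160 binary,
50 three-state, 20 four-state, 9 five-state; 30% of multistate
characters ordered; 10% missing cells, 2% polymorphic), and five
molecular markers of 1,078 / 367 / 1,246 / 1,101 / 481 bp with codon
structure on the coding four. Tests and examples scale these counts
down (typically 15–30 taxa, tens of characters, tens to hundreds of
trees per run) so the full suite runs in well under a minute; the
statistical structure, not the size, is what the assertions exercise.

The true tree is a Yule backbone over the clade stubs with each stub
expanded into its own Yule crown. Depth is structured: crowns occupy
`crown_fraction` (default 0.3) of the root-to-tip depth, every clade
stem receives an additional `stem_fraction` (default 0.2), and the
remainder is shared backbone. The explicit stem component matters: if
crowns are grafted with no depth control, a clade's stem can come out
near zero, and then even a perfect synapomorphy (state fixed in the
clade, absent elsewhere) reconstructs ambiguously at the crown MRCA —
the single change can no longer be confidently placed on the stem.
With an appreciable stem the reconstruction pins the crown ancestor,
which is the regime the index pipeline (and any study constraining
clades it intends to diagnose) presumes. Mean root-to-tip depth
defaults to 0.5 expected changes, a typical morphological scale.

Characters are simulated forward along the tree by the same CTMC the
inference uses, with per-character rates drawn from the discrete-gamma
categories and every internal node's state recorded; masking to
missing and polymorphism (true state plus an adjacent or random other
state) happens after the truth is recorded. Planted clade-diagnostic
characters — binary, fixed at 1 in one clade and 0 elsewhere, unmasked
— give the end-to-end recovery tests a known answer. DNA evolves under
HKY with designated clades switching to a different GC equilibrium on
their stem branch, a proportion of invariable sites, and a faster
third codon position.

Pseudo-posterior samples replace real MCMC: each sampled tree is the
true topology (branch lengths jittered log-normally, median 1) or,
with probability p, a random NNI neighbour. Because one NNI disrupts
exactly one internal split, every true split has intended frequency
1 − p/(n−3) on n taxa, giving the summarizers analytically known
targets — the reason this design was chosen over running a real
sampler. What the generator does *not* emulate: correlated characters,
autocorrelated MCMC samples (pseudo-posterior draws are independent),
within-character rate variation along the tree, indels, and model
misspecification. Passing tests therefore demonstrate correctness of
the summaries, the reconstruction machinery and the indices under the
generating model, not robustness of Mk reconstruction on real
morphology.

All generators are deterministic in the recipe seed; each derives its
stream from a fixed offset of it, so regenerating any single component
reproduces identical bytes.

## Numerical choices and degenerate inputs

Transition probabilities clip negative entries from the
eigendecomposition (magnitude ~1e-16) to zero and renormalize rows.
Pruning rescales a node's partials whenever their maximum leaves
[1e-12, 1e12]; a category under which the data are impossible (an
ordered character needing a forbidden jump) contributes −Inf on the
log scale and drops out of the category mixture. Infinite branch
lengths return the stationary (uniform) kernel. Fewer than four leaves
yield an empty split set rather than an error. Polytomies are allowed
everywhere; constraint logic and consensus construction are
polytomy-safe. Outgroup rooting places the root on the outgroup edge;
a non-monophyletic outgroup falls back to rooting at the outgroup MRCA
with a logged message. Missing PP entries in index computation raise
an error naming the node — never a silent zero-fill.

## Known limitations

Hypothesis probabilities are sample-frequency estimates; very rare
hypotheses (true PP below ~1/N) are only bounded, not estimated.
Ancestral PPs average over trees at a fixed gamma shape rather than
over per-generation sampled shapes; an `alpha` per analysis is
accepted and recorded, which matches the fixed-model reconstruction
setting but not samplers that integrate over the shape. The consensus
builder targets majority-rule thresholds (> 0.5); it does not
implement greedy extensions below that. The NEXUS reader covers the
DATA/CHARACTERS/ASSUMPTIONS/SETS/TREES constructs used by
morphological matrices and MrBayes output, not the full NEXUS
standard.
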