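---
title: "Models and methods behind mitolin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitolin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolin)
```

# Scope

mitolin infers clonal structure in single-cell populations from somatic
mitochondrial-DNA mutations. The pipeline has six analytical layers: a
generative simulator with full ground truth; endogenous-UMI (eUMI) consensus
variant calling; variant-matrix algebra (heteroplasmy, binarization,
prior-weighted Jaccard distances, LSI); neighbour-joining phylogeny with
maximum-likelihood variant-to-branch assignment and tree-cut clonal groups;
random-walk-with-restart (RWR) assignment of progeny to stem-cell clones on a
mutual-KNN graph; and clone-level statistics (output activity, lineage bias,
state enrichment, clonal diversity, clade expansion, a fitness proxy, and
loss-of-chromosome-Y detection).

This vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the simulation-based tests do and do not
demonstrate about real data.

# The generative model

`simulate_lineage()` runs a neutral molecule-level process. Every cell holds
a population of mtDNA genome copies (`mt_copies`, default 300, drifting
thereafter). At each cell division:

1. every molecule replicates once; each replication acquires `Poisson(mu)`
   substitutions at uniform positions of a circular genome
   (`genome_length` = 16569 by default, with a synthetic random reference);
2. the `2n` molecules are partitioned binomially (p = 1/2) between daughters;
   per-variant carrier counts are therefore hypergeometric given the
   daughter's total.

This is the simplest neutral drift model consistent with single-copy mutation
birth and random mitotic segregation; recurrent mutation is allowed, which
produces the homoplasy the prior-weighted distance is designed to absorb.

**Clone structure.** Founders are not independent: a single root cell divides
for `founder_depth` divisions (default 50, a developmental-history scale)
along a random division tree whose leaves are the `n_clones` clone founders;
sampled cells sit `divisions_per_cell` (default 20) divisions below their
founder. Without the founder phase, clones would carry almost no high-
heteroplasmy clone-defining variants and would be near-unidentifiable by any
method; with it, founder variants drift to appreciable heteroplasmy and are
shared clone-wide, which is the biological premise of mtDNA lineage tracing.

**Calibration.** The only calibrated parameter is `mu` = 0.011 substitutions
per genome replication, chosen once so that the default population (78 clones
x 64 cells, capture rate 0.17) shows a median of ~9 *detected* variants per
cell, the burden regime reported for deep single-cell mtDNA profiling of
human haematopoietic cells. Detection here means presence on at least one
captured molecule (`truth_variant_matrix()`), with per-cell captured totals
binomial and per-variant counts hypergeometric.

**Reads.** `simulate_reads()` emits eUMI-structured reads: each captured
molecule gets a fragment (length ~ Normal(250, 60) bp, truncated at 50 bp;
fragments never span the circular origin), a shifted-Poisson read count
(minimum 1, mean `reads_per_eumi_mean` = 4.8) alternating plus/minus mates,
the molecule's variants inside the fragment, and independent per-base errors
at `seq_error_rate` (default 1e-3). Variants are assigned to captured
molecules independently (hypergeometric counts); within-molecule variant
linkage is not modelled, and no downstream operation consumes it. The read
layer operates at fragment scale: a molecule contributes one fragment, so
per-position copy coverage is far below per-cell genome capture. Cell-level
analyses therefore use the capture-thinned truth matrix, while the read layer
exercises the consensus caller at molecule scale.

**States.** `simulate_states()` draws per-clone lineage proportions once from
`Dirichlet(bias_alpha)` and reuses them at both timepoints — the "consistent
lineage preference" structure the bias statistics are designed to detect.
Progeny lineages are multinomial; a fraction `frac_hsc` of cells is flagged
as stem cells with no lineage.

**What the simulator does not emulate:** selection on mtDNA variants, cell
death, copy-number regulation, PCR chimeras/jackpots, alignment artefacts,
base-quality structure, doublets, or contamination. Passing tests on this
generator show algorithmic correctness under a neutral, well-behaved model,
not robustness to every artefact of real libraries.

# Consensus calling and filtering

The eUMI of a molecule is the exact (cell barcode, fragment start, fragment
end) triple; no fuzzy endpoint merging is attempted, and the resulting
collisions (independent molecules drawing the same key; rare at realistic
molecule counts, and benchmarked against a birthday-model estimate in the
test suite) are tolerated. Groups below `min_group_size` (default 2) are
rejected. A non-reference base is retained only with majority support at
consensus score >= `consensus_threshold` (default 0.75) and, when the group
contains both mates, support on both strands; a group whose majority base
fails the threshold is rejected as ambiguous. The `specific` preset raises
the group-size minimum to 3 and requires unanimity.

Variant-level filters then remove: blacklisted positions (defaults 300-316
and 3106-3110, the standard mtDNA artefact tracts), putative
germline/haplogroup variants (carried at mean heteroplasmy >=
`germline_het` = 0.9 by >= `germline_cell_frac` = 0.9 of position-covered
cells), and variants in fewer than `min_cells_per_variant` = 2 cells. These
numeric defaults are design choices exposed in `filter_config()`; they encode
"stringent multistep filtering" but are not canonical constants.

The per-sample eUMI filtering rate is defined as retained groups / all
groups. Mutation burden for cell *i* in sample *j* is
`n_mutations / (eumi_filter_rate_j * coverage_i)` with coverage the mean
mtDNA copies per position (total retained fragment length / genome length).
Note that re-observing every molecule twice doubles coverage but not distinct
mutations, so burden halves: burden corrects detected counts for technical
depth, it is not a per-molecule rate.

Mutational signatures classify each substitution with a pyrimidine reference
convention: the reference sense strand is taken as the light strand; a
purine-reference substitution is complemented, attributed to the heavy
strand, and its trinucleotide context reverse-complemented (circular at the
genome ends).

# Distances, priors and embeddings

The prior of variant *i* is `1 - average mutation rate across donors`
(`variant_priors()`, defaulting to 1 without a cross-donor table). For binary
profiles x, y the weighted Jaccard distance is

$$D(x,y) = 1 - \frac{\sum_{i \in x \cap y} \mathrm{prior}_i}
                    {\sum_{i \in x \cup y} \mathrm{prior}_i}.$$

The denominator runs over the union of the two cells' variants: a
denominator over all variants would make the distance between two cells
depend on variants neither carries. With unit priors this is the classical
Jaccard distance (tested against a set-based oracle). Cells with empty
profiles sit at distance 1 from every non-empty cell and 0 from each other.

LSI (`lsi_embed()`) uses row-normalized term frequency,
`IDF = log(1 + n_cells / df)`, and a truncated SVD (top 30 components by
default, none dropped, no post-hoc log); signs are fixed so each component's
largest-magnitude loading is positive. This is the common single-cell LSI
dialect; it is a convention, not a canonical transform.

# Phylogeny, branch assignment and clonal groups

Neighbour joining (via ape) runs on the weighted-Jaccard (or LSI-Euclidean)
distance matrix after appending an artificial outgroup cell with an empty
mutation profile — distance 1 to every real cell under weighted Jaccard —
which roots the tree and is then removed. Negative NJ branch lengths are
clamped to zero. Rooting by empty-profile outgroup is a design choice: the
mutation-free ancestral state is the natural root of a somatic-mutation tree.

Variants are placed on edges with a generic sensitivity/false-positive
likelihood: for carrier set O and the clade C_e under edge e,

$$\log L(e) = |O \cap C_e|\log s + |C_e \setminus O|\log(1-s)
            + |O \setminus C_e|\log f + |\text{rest}|\log(1-f),$$

with defaults s = 0.9, f = 0.001 and per-variant assignment probabilities the
softmax of log L over all candidate edges (the root edge, covering all
leaves, is a candidate). This reconstructs the intent of
maximum-likelihood branch assignment from first principles; it is not a port
of any particular package's internals. A variant is confidently placed when
its probability reaches `confident_prob` (default 0.6). An empirical
false-positive-rate estimation mode (from decoy variants near blacklisted
tracts) was considered and not built: the simulator does not generate the
artefact structure such decoys measure.

`cut_tree()` selects minimal (deepest) disjoint clades with >= `m` cells
whose based edge carries >= `n` confidently assigned variants (defaults
m = 50, n = 1, P = 0.6), then discards clones below the dump threshold `D`.
When nested clades both qualify the deepest one wins, matching the minimal
clade-unit reading. For benchmark populations whose true clones hold 40
cells, analyses use m = 30, since a 40-cell clone can never form a 50-leaf
clade; the cut parameters are analysis knobs, not constants.

# Propagation and clonal assignment

`build_mknn()` links two cells when each is in the other's k nearest
neighbours (k = 30 by default; the neighbourhood size is a convention, chosen
as the common single-cell graph scale) by Euclidean distance in the LSI
embedding. `rwr_propagate()` iterates
`p <- (1 - r) W p + r p0` with W column-stochastic over the unweighted
adjacency (degree-0 nodes self-loop), p0 uniform on the seed set, and
restart r = 0.05 — the damping factor read as the restart probability.
Iteration stops when the L1 change drops below 1e-6 (iterative and
closed-form solutions agree to 1e-8 on graphs of up to 200 nodes in the
tests; mass is conserved to 1e-9 because W is column-stochastic).
`assign_clones()` propagates every clonal group as one column of a batched
iteration, normalizes each cell's scores across clones, assigns the argmax,
and leaves cells below the 0.7 maximum-probability cutoff unassigned. Seed
cells stay in the network during benchmarking (self-assignment); a
leave-self-out mode would estimate generalization instead and is not the
reported benchmark.

# Clone-level statistics

*Output activity* counts assigned progeny per clone and timepoint,
normalized by the clone's stem-cell count, with the ranked
cumulative-contribution curve (anchored at 0), top-vs-bottom decile fold
change, and the Pearson correlation between timepoints.

*Lineage bias* tests each clone x lineage against the pooled background
proportions with an **exact two-sided binomial test** per timepoint, combines
the two timepoints with Fisher's method (chi-squared, 4 df), and converts
combined p-values to Storey q-values. A pair is *biased* only when the
fold-change direction agrees at both timepoints and q < 0.2 (`*` 0.05-0.20,
`**` 0.01-0.05, `***` < 0.01). Sidedness was a genuinely open design point:
a p-value sided toward the observed direction is anti-conservative under the
null (its distribution is compressed toward 0), and Fisher-combining two such
p-values collapses the Storey pi0 estimate, inflating the flagged fraction
far beyond the nominal FDR. The two-sided test with a separate
direction-consistency requirement restores calibration — the packaged null
simulation holds the clone flag rate within Monte-Carlo error of the nominal
level — while preserving the directional meaning of "bias".

*Clone-to-state enrichment* uses per-timepoint hypergeometric tails and log2
fold changes, Fisher combination, and the flag rule combined p < 0.01, FDR <
0.05, and log2FC > 0.25 at both timepoints.

*Lineage-informative variants* are kept when any pairwise trajectory
comparison (carriers in A among carriers in A+B against n_A/(n_A+n_B))
yields p <= 0.05; variants whose comparisons are all non-significant are
treated as randomly distributed and dropped. The cell-type origin analysis
then averages, per query type, the target-type proportions within each
cell's weighted-Jaccard KNN, with z-scaled rows and hierarchically clustered
query order.

Because Bioconductor's qvalue package is not a dependency of this package,
`storey_qvalue()` implements the Storey procedure directly: the lambda-grid
pi0 estimator smoothed with a natural cubic spline and evaluated at
lambda = 0.95, falling back to pi0 = 1 (Benjamini-Hochberg) for families
under 100 tests where the smoother is unstable.

*Clone matching across timepoints* pairs clones greedily by Jaccard
similarity >= 0.5 of their defining-variant sets — a symmetric, idempotent
rule chosen because re-observation of a clone is defined by its variants,
not its cells.

# Diversity, expansion, fitness, LOY

Shannon diversity uses the natural log of clone-size proportions. The
clade-expansion test scores every non-root internal node against its sisters
under the neutral-coalescent clade-size law

$$P(B = b \mid n, m) = \binom{n-b-1}{m-2} \Big/ \binom{n-1}{m-1},$$

with the upper tail as p-value; expanded clades are maximal flagged clades
(p < 0.01) holding >= 5% of cells (an absolute-size alternative is
available). The probabilities sum to one exactly for all n <= 50 (tested)
and the test's type-I rate on neutral coalescent topologies is calibrated at
alpha = 0.01.

The per-leaf fitness score is a local-branching-index proxy: exponentially
discounted tree length accumulated by up/down message passing with timescale
tau (default 0.3 x mean root-to-leaf depth). It ranks cells inside dense,
recently expanded clades above isolated long branches; it is a tree-shape
statistic, not a probabilistic fitness estimate, and no fitness coefficients
are claimed.

LOY calls use a binomial model of per-cell chrY fragment counts out of total
fragments, with the expected fraction estimated from the aggregate ratio
(median-of-ratios optional, robust when a substantial LOY fraction would
contaminate the baseline): a cell is LOY when its count is 10-fold below
expectation *and* the binomial lower tail is below 0.001. Clade enrichment
reports LOY density, a z-score under binomial variance (an empirical
variance would also be defensible; binomial was chosen for its exactness
under the stated model), a one-tailed binomial p and Storey q-values.

# Problem sizes and determinism

The packaged tests and the acceptance script use: consensus benchmarking at
~6,000 molecules; clone recovery at 2,000 cells (50 clones x 40 cells);
propagation benchmarking at ~5,000 cells in 78 clonal groups averaged over
three seeds; 500 neutral 200-leaf trees for expansion calibration; and
150-clone cohorts for bias calibration. These sizes were chosen as the
smallest populations in which each statistic reaches a stable regime.
Every stochastic stage derives its stream from a single seed
(sub-streams at fixed offsets), so identical seeds give byte-identical
outputs; the truncated SVD is seeded and sign-fixed.

# Known limitations

- The consensus caller handles substitutions only — no indels, no
  base-quality weighting, no realignment.
- eUMI keys are exact; endpoint-jittered duplicates of one molecule are
  counted as distinct molecules.
- The branch-assignment likelihood treats cells independently given the
  clade, ignoring shared-coverage structure.
- The fitness proxy and the LOY z-score are heuristics on top of exact
  primitives; their p-values are not calibrated jointly with tree
  uncertainty.
- Clone recovery quality depends on founder-phase heteroplasmy; populations
  whose clones were established without deep shared history (low
  `founder_depth`) are intrinsically hard for any mtDNA method, and the
  package will return few confident clones there.
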