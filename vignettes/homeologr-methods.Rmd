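---
title: "Scoring allopolyploidy hypotheses and companion analyses with homeologr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring allopolyploidy hypotheses and companion analyses with homeologr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeologr)
```

## The problem

Allopolyploid lineages arise when two diverged diploid species hybridize
and the hybrid retains both parental chromosome sets.  Each low-copy
nuclear gene is then expected to be present as a pair of *homeologs*, one
per parental subgenome (conventionally tagged A and B).  Given a handful
of such gene trees, karyotypes and genome sizes, one wants to answer: did
the polyploid taxa arise through hybridization at all, between which
diploid lineages, and once or twice?  `homeologr` implements the whole
desk-scale chain of analyses around this question: hypothesis scoring by
gene-tree/network reconciliation, hypothesis enumeration and ranking,
ancestral-state stochastic mapping of discrete traits, ploidy
classification, and post-VCF genetic-diversity analysis, together with
synthetic-data generators so every stage can be exercised and validated
without external data.

## The reconciliation score

A hybridization scenario is represented as a rooted phylogenetic network
with at most two hybridization nodes.  For scoring, the network is
expanded into its **MUL tree** (multi-labeled tree): every taxon below a
hybridization appears twice, once under each parent edge, tagged A (first
parent) and B (second parent).  A no-hybridization hypothesis is simply a
species tree.

Given a gene family (a rooted binary gene tree plus a map from gene
copies to species), each copy of a repeated species must be assigned to
one of that species' MUL leaves.  For a fixed assignment the family is
embedded by the classical LCA (lowest-common-ancestor) mapping, and
events are counted:

* a gene node is a **duplication** iff its image equals the image of one
  of its children;
* along each gene edge, **losses** equal the number of host edges crossed
  between the two images, minus one at speciation nodes.

The cost is `c_dup * D + c_loss * L` with both unit by default, and the
score of the family against the hypothesis is the *minimum over all
assignments*; a hypothesis' total score sums these minima over all
families.  Lower is better; a congruent family scores 0.

Two deliberate conventions, stated because the score depends on them:

* **Unsampled taxa are free.**  Losses are counted on the host tree
  restricted to the subtree spanning the images of the sampled leaves.
  Real gene sets rarely cover every species for every gene; charging
  every absence as a loss would let sampling gaps swamp the hybridization
  signal.  Absolute scores are therefore comparable only across
  hypotheses for the same data, which is the only use made of them.
* **Deterministic tie-break.**  Among equal-cost assignments the
  lexicographically smallest is returned (ambiguous leaves ordered by
  label, A before B), so repeated runs are identical.

The minimization is an exact enumeration over the `2^m` assignments of
the `m` ambiguous leaves, in compiled code.  A second, pure-R exhaustive
implementation (`brute_force_mul_score()`) is exported and the test suite
asserts equality of the two routes on hundreds of randomized instances;
`mul_reconcile()` additionally re-scores its optimum with the R scorer on
every call.

## Hypothesis enumeration

The search space mirrors how such an analysis is set up in practice:

* **0 events** — one hypothesis per supplied backbone; typically two
  backbones, with the polyploid clade placed at the position implied by
  the A or the B subgenome (labelled `T1`, `T2`).
* **1 event** — the better-scoring backbone is pruned of the polyploid
  clade; the clade is re-grafted as a unit into every unordered pair of
  distinct edges of the pruned backbone such that at least one edge is
  the pendant edge of a candidate parent ("involving" the candidates).
* **2 events** — the clade is split into its two root subclades, each
  independently receiving a qualifying edge pair.

Attachments to the root edge are not enumerated (a root attachment is
indistinguishable from rerooting at desk scale), and the polyploid clade
is split only at its root: this is the smallest space containing every
biologically distinct placement of an intact one- or two-origin polyploid
group.  Edges are identified by the set of taxa below them, so hypothesis
labels are stable across serializations.

The *preferred* hypothesis is the one with the fewest hybridization
events whose score is within `delta_threshold` (default 5) of the global
minimum.  This encodes the parsimony argument that a marginal score
improvement — a few loss events' worth — does not justify postulating an
extra reticulation; with `delta_threshold = 0` the preference degenerates
to the argmin.

```{r scan}
net <- toy_allopolyploid_network()
dec <- homeologr:::network_events(net)
T1 <- graft_clade(dec$backbone, dec$events[[1]]$clade, "P")
T2 <- graft_clade(dec$backbone, dec$events[[1]]$clade, "S")
fams <- simulate_gene_families(net, n_families = 4, dup_rate = 0.2,
                               loss_rate = 0.2, seed = 1)
scan <- run_scan(list(T1, T2), c("H1", "H2"), c("P", "S"), fams)
head(tidy(scan))
scan$preferred
```

## The synthetic gene-family generator

`simulate_gene_families()` is first-class, tested code, and the study
conditions it encodes are fixed rather than tunable knobs:

* A single ancestral gene enters at the network root; along every edge
  each copy duplicates and is lost as a Poisson birth–death process
  (rates per copy per unit branch length).
* At a hybridization node the hybrid inherits **every** extant copy from
  **both** parental lineages — a true genome merger, matching the
  AB-subgenome structure of allopolyploids, not an introgression model
  that samples one parent per copy.
* Families with fewer than two surviving copies are redrawn; a
  reconciliation needs at least two leaves.  This conditioning slightly
  biases event counts upward at high loss rates, which is irrelevant at
  the rates used here.

The bundled `toy_allopolyploid_network()` has eight taxa, one
hybridization between the lineages of the diploids `P` and `S`, and all
edges 0.25 time units long.  With the default rates of 0.2 events per
unit length this yields on the order of one duplication and one loss per
family: polyploid species retain a clean homeolog pair in most families,
with occasional extra copies or missing homeologs — the regime in which
low-copy nuclear genes are actually useful for this question, and the
regime reported for real allopolyploid groups.  At these settings the
generating network is recovered as the top-ranked hypothesis in ≥90% of
replicates (50 replicates of 4 families; measured by the acceptance
script), and with the rates set to zero the generating network is the
unique zero-score hypothesis among all 308 enumerated ones.

What the generator does *not* emulate: sequence-level evolution and gene
tree estimation error (gene trees are emitted directly), incomplete
lineage sorting, and gene conversion between homeologs.  A passing
recovery test therefore demonstrates the correctness and discriminatory
power of the scoring machinery, not robustness to phylogenetic error in
real data.

## Ancestral states by stochastic mapping

Discrete traits (ploidy level, ecology, stem nodulation and the like)
are mapped under a continuous-time Markov (Mk) model.  The rate model
defaults to equal rates (ER) with a uniform root prior — both
configurable; nothing in a typical trait table justifies the extra
parameters of an all-rates-different model, though `fit_mk()` offers it.
Unknown states (`"-"` in trait tables) enter the pruning pass as all-ones
partial likelihoods, i.e. they constrain nothing.

`stochastic_map()` samples complete character histories from their
posterior: node states are drawn backward from the pruning conditionals,
then each branch history is drawn conditional on its endpoints by
**uniformization** (a Poisson number of candidate jumps at the
uniformized rate, thinned of self-transitions).  Rejection sampling was
deliberately avoided: it stalls on short branches whose endpoints force a
change.  Histories are reproducible given a seed; `n_maps` defaults to
10, a common choice for visual summaries, while the statistical checks in
the test suite use 2000 draws to pin the sampled root-state frequency to
the exact pruning-algorithm marginal within ±0.03.

The mapping functions require a strictly bifurcating input tree with
branch lengths.  Polytomies (e.g. a consensus-tree polytomy) must be
resolved upstream, by the caller, because any automatic resolution would
silently change the mapped histories.

## Ploidy classification

`classify_ploidy()` is a pure lookup of the established attributions
20→2x, 28/38/40→4x, 56/76→8x, 60→6x.  Dysploid counts (28, 38) are
mapped to 4x because that is their established attribution; any count
outside this set returns `"unknown"` rather than a `2n/2x` rounding — a
dysploid origin cannot be resolved from a count alone.  Genome sizes are
converted with 1 pg DNA = 978 Mb applied to half the 2C value, and the
computed value is always reported at full precision (no prose rounding).
Copy-count consensus uses a 0.5 threshold on the fraction of two-copy
genes ("almost all genes duplicated"), configurable; when karyotype and
copy counts disagree the karyotype call wins and a conflict flag is
raised.

## Genetic diversity from VCF genotypes

The post-variant-calling stage filters biallelic SNPs, removing variants
with more than 10% missing calls or a minor allele frequency below 0.01
(MAF computed on non-missing calls; the threshold is *keep ≥ 0.01*,
matching common tooling practice).  Distances are identity-by-state:
`1 − mean allele sharing` over pairwise-complete variants, with no
imputation.  Ordination is classical metric MDS (double-centered squared
distances, eigendecomposition; negative eigenvalues are excluded from
axis selection), and group assignment — a surrogate for drawing circles
on the ordination by eye — is k-medoids with a user-supplied group count,
never auto-selected.

The genotype generator draws group allele frequencies from a
Balding–Nichols beta distribution around uniform ancestral frequencies;
at divergence `F = 0.3`, 500 SNPs and 20 samples per group, group
recovery is exact (adjusted Rand index 1), while at `F = 0` the first
MDS axis carries less than 20% of the positive eigenvalue mass — both
properties are asserted in the tests.

## Numerical and degenerate-input choices

* Transition matrices use the eigendecomposition of `Q`, falling back to
  a Padé matrix exponential when `Q` is defective; negative entries from
  roundoff are clamped to zero.
* The pruning pass rescales partial likelihoods per node, so likelihoods
  of large trees do not underflow.
* `fit_mk()` optimizes the log rate on a bounded interval; a monomorphic
  trait yields the boundary fit at rate 0 with a warning, not an error.
* A zero-length or zero-rate branch whose endpoints are forced to differ
  raises an "impossible history" error rather than looping.
* Polytomies anywhere a binary tree is required are an error, never
  silently resolved.
* Newick parsing rejects unbalanced input naming the offending position;
  extended-newick hybrid tags must occur exactly twice each, and at most
  two hybridization events (no stacked events) are supported.

## Problem sizes used in validation

The shipped checks run at desk scale: 200 randomized oracle-equivalence
instances (gene trees ≤ 10 leaves, ≤ 3 repeated species), 50 scan
replicates of 4 families on the 8-taxon network (~308 hypotheses each),
2000 stochastic maps on a 5-leaf tree, 500-SNP genotype panels of 60
samples.  These sizes were chosen so that each check is statistically
decisive for the property it tests while the whole suite remains quick to
run; all of them are generated in code at run time.

## Known limitations

* Reconciliation models duplication and loss only — no transfers, no
  incomplete lineage sorting, no probabilistic reconciliation.
* At most two hybridization events, no stacked events, and one consensus
  gene tree per gene (no tree distributions).
* The assignment search is exponential in the number of ambiguous gene
  copies (fine for ≤ ~20 copies of repeated species; refused beyond).
* Absolute hypothesis scores depend on the unsampled-taxa convention
  above and on how the input gene trees were rooted; only score
  differences between hypotheses on the same data are meaningful.
* The MDS stage assumes biallelic dosages; multiallelic records are
  skipped, not decomposed.
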