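---
title: "Predicting gene function from genomic neighbourhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene function from genomic neighbourhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funscape)
```

## The model

`funscape` predicts Gene Ontology annotations for genes using a single kind
of evidence: the gene's position relative to already-annotated genes of the
same genome. The premise is biological — functionally related genes cluster
spatially in eukaryotic genomes — and the machinery is deliberately blind to
sequence, expression or interaction data.

The genome is modelled as a collection of chromosomal arms, each an ordered
string of protein-coding genes sorted by transcription start site. All
distances are measured in genes. This makes the representation invariant to
assembly scale and intergenic architecture; it also means single-gene arms
carry no neighbourhood information at all (their features are defined as 0,
see *Numerical conventions*).

The core statistic is the local enrichment of a term $x$ around a gene $j$
for a window half-width $w$:

$$E_{jxw} = \frac{k/n}{M/N}$$

with $N$ genes on $j$'s arm, $M$ of them annotated with $x$, $n$ genes in
the window ($w$ to each side, truncated at arm boundaries) and $k$ annotated
genes among them. The focal gene is excluded from both $n$ and $k$: a
training gene's own annotation would otherwise leak its label into its
feature vector, and since evaluation genes are annotation-masked, including
the focal gene would also shift features between training and evaluation
genes. This exclusion is a deliberate design choice and is configurable in
`window_members()`.

Per gene and target term, the Functional Landscape Array (FLA) stacks these
enrichments into a matrix with one row per half-width (5, 10, 20, 50, 100
genes by default) and one column per term related to the target. Two column
sets are supported, because the natural choices differ: the default
`relatives_down` uses the target, its parents, its siblings and all its
descendants; `relatives_up` replaces descendants with ancestors. Both are
defensible — descendants concentrate specific signal near the target,
ancestors supply broad context — so the choice is surfaced as configuration
rather than silently fixed. Columns are ordered target-first then
lexicographically, and the matrix flattens row-major (width-major) into the
classifier's feature vector; both orderings are fixed because model
reproducibility depends on them.

## Training and scoring

Genes are split uniformly at random into 80% training (T) and 20%
evaluation (E); the split is unstratified, and `round()`'s round-half-even
rule decides the boundary count. A binary random forest is trained for every
term with at least 40 annotated genes in T and 10 in E (counted on
up-propagated annotations — eligibility floors refer to the closure, since
training positives are defined on it). The root is never modelled.

Negatives follow the siblings policy: genes annotated with a sibling or
uncle of the target but not the target itself. These are the most
informative negatives — genes known to do something adjacent but different.
When a target has no sibling/uncle genes at all, the documented fallback
samples negatives uniformly from training genes lacking the target, and the
event is logged.

Hyperparameters (tree count, maximum depth, split criterion) are chosen by
grid search with stratified 3-fold cross-validation maximising the positive
class's F1. The default grid spans trees {100, 200, 500} and depth
{5, 10, unlimited}. The split-criterion axis deserves a note: the ranger
backend implements gini, extra-trees and Hellinger splitting but not an
entropy criterion, so the default grid fixes gini and exposes the axis in
`default_grid()` for the criteria the backend supports. With a single-point
grid, cross-validation is reporting only and can be skipped (`folds = 0`).

Every term's seed is derived deterministically from a master seed and the
term id, so training order (or parallelisation) cannot change results.
Per-term failures are logged and skipped rather than fatal — with hundreds
of terms, a handful of degenerate training sets should not kill a run.

Scores are post-processed into DAG consistency by top-down min-propagation:
in topological order from the root (implicit score 1), each term's score is
capped at the minimum of its parents' effective scores; unscored
intermediate terms pass their parents' constraint through. This is the
minimal correction guaranteeing the true-path constraint (no gene scores
higher on a term than on its ancestors), it is idempotent and never
increases a score, and it is isolated behind `enforce_hierarchy()` so that
alternative reconciliation schemes can be plugged in. In practice the
pass-through case is moot: propagated annotation counts are monotone up the
DAG, so the eligible term set is ancestor-closed and every scored term's
ancestors are scored (or are the root).

## Evaluation

Predictions are evaluated with hierarchical precision and recall over
ancestor-closed term sets: for each evaluation gene, the predicted set at
threshold $\theta$ is the root plus every term scoring $\ge \theta$, the
true set is the gene's propagated annotation set plus the root, and

$$hPrec(\theta) = \frac{\sum_i |P_i(\theta) \cap T_i|}{\sum_i |P_i(\theta)|},
\qquad
hRec(\theta) = \frac{\sum_i |P_i(\theta) \cap T_i|}{\sum_i |T_i|}$$

with hF1 their harmonic mean (0/0 defined as 0) and hF-max the maximum over
the threshold grid. The root is added to *both* sides: adding it only to
predictions would let every threshold buy free recall, and symmetric
inclusion keeps $hPrec \le 1$ trivially while never rewarding the root.
The threshold grid is 0 to 1 in steps of 0.01 — fine enough to subsume any
coarser reporting resolution.

The null model against which everything is judged assigns each term its
relative annotation frequency among training genes as the score of every
gene — the strongest predictor available to a method that knows term
prevalence but nothing about individual genes. The frequency base is the
training set (the information available at training time); a genome-wide
base is selectable. The ratio of trained to null hF1 across thresholds
summarises how far from random the arrangement of functions along the
genome is; grid points where the null hF1 is 0 are excluded from the argmax
rather than treated as infinite, and ties resolve to the smallest
threshold.

Final predictions keep pairs scoring at least the ratio-maximising
threshold $\theta^\*$, then retain only the most specific term per branch
per gene (no emitted term is an ancestor of another emitted term for that
gene); the root is never emitted. Genes in scores but absent from the truth
store are an error by contract, so pipeline evaluation restricts the curve
to evaluation genes with at least one annotation — the CAFA convention —
while predictions are issued for every evaluation gene.

## The synthetic generator

`make_toy_ontology()` builds a rooted tree (optionally with random extra
parents, mimicking multiple inheritance) and `make_clustered_genome()`
plants spatial signal: each leaf term draws a gene count from a Poisson
distribution with mean `n_genes * mean_terms_per_gene / n_leaves`, places a
fraction $\rho$ (`cluster_strength`) of those genes in contiguous runs at
random arm positions and scatters the rest uniformly. Genes may carry
several leaf terms; annotations are generated at the leaves and then pushed
through the ordinary `propagate()` path, exercising the same code as real
data. At $\rho = 0$ placement is exchangeable with uniform assignment;
`shuffle_annotations()` permutes whole annotation sets across gene
positions, preserving term frequencies exactly while destroying all spatial
structure.

Defaults (2,000 genes on 4 arms, a 3-level branching-3 ontology, 1.5 leaf
terms per gene on average, $\rho = 0.8$, one run per term) are chosen so
that a desk-scale genome has arm lengths, term counts and annotation
densities at which the 40/10 eligibility floors and the 5–100-gene windows
all remain meaningful. What the generator does *not* emulate: realistic
chromosome-length and term-frequency distributions, correlated or nested
clusters spanning related terms, annotation noise and incompleteness, and
evidence-code structure. Passing the recovery tests therefore shows the
machinery extracts planted spatial signal correctly — not that any
particular real genome carries that much signal.

## Numerical conventions and degenerate inputs

* $M = 0$ (term absent from the arm) defines $E = 0$, not `NaN`: $k$ is
  necessarily 0 and "no signal" is the semantically correct feature value.
* $n = 0$ (single-gene arm) has no defined enrichment; scalar queries
  return `NA` with a warning, and FLAs for such genes are all-zero with a
  warning.
* Windows truncate at arm ends and $n$ reflects the truncated count, so the
  statistic stays well-defined near telomeres and centromeres; windows
  never cross arms.
* Identical transcription start sites order lexicographically by gene id,
  making the genome model a pure function of the record set.
* Depth is the shortest path to the namespace root (longest-path available
  by flag); `part_of` edges are traversed as hierarchical by default and
  can be disabled.
* All tie-breaks (grid points, thresholds, hF-max) resolve to the first /
  smallest candidate.
* Ranks are 0-based in memory; every file output reports 1-based positions
  and says so in a header.

## Problem sizes used in the shipped checks

The test suite verifies the enrichment statistic against a brute-force
sliding recount on 200 random genomes (arms up to 300 genes, up to 10
terms, all five half-widths, tolerance $10^{-12}$), the hierarchical
metrics against direct set enumeration on 500 random instances (up to 20
genes, 15-term DAGs), consistency enforcement on 1,000 randomized score
matrices, and signal recovery on 50 seeds of the default synthetic genome —
with single-point forests (50 trees, depth 10, no cross-validation), sizes
at which the full battery runs in minutes on one CPU while still exercising
every stage at the documented study conditions. The acceptance script runs
one full pipeline at the same genome scale with a 2×2 grid search and
3-fold cross-validation. These sizes are the package's own desk-scale
choices; every knob scales up unchanged.

## Known limitations

* The method predicts only terms above the eligibility floors — rare,
  specific terms are out of reach by construction, and predictions
  concentrate at intermediate depths.
* Arms with few genes yield weak or undefined features; organisms with
  many micro-scaffolds will dilute the signal.
* The null model is per-term frequency; stronger baselines (e.g. sequence
  homology) are out of scope here.
* Hierarchy enforcement by min-propagation is one of several published
  reconciliation schemes; others (isotonic regression, Bayesian correction)
  can be swapped in behind the same interface but are not implemented.
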